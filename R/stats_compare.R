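## Statistical comparisons: position ANOVA with subject as a random factor
## (repeated-measures form), Bonferroni-adjusted pairwise post hocs, paired
## and independent t-tests, percent-change and signed latency-change
## contrasts. Significance is judged at alpha = 0.05 throughout.

#' Assemble a one-row statistics result
#' @noRd
stats_result <- function(test_name, statistic, df1, df2 = NA_real_, p_value,
                         adjusted_p = NA_real_, contrast = "", alpha = 0.05) {
  eff_p <- if (!is.na(adjusted_p)) adjusted_p else p_value
  data.frame(test_name = test_name, statistic = statistic,
             df1 = df1, df2 = df2, p_value = p_value,
             adjusted_p = adjusted_p, significant = eff_p < alpha,
             contrast = contrast, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p Raw p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Position ANOVA with subject as a random factor
#'
#' Condition is the fixed factor and subject the random (blocking) factor;
#' with one observation per subject x condition cell this is the
#' repeated-measures ANOVA, fitted as `aov(value ~ condition +
#' Error(subject))`. If the omnibus is significant at `alpha`, all pairwise
#' condition contrasts are tested with paired t-tests and Bonferroni
#' adjustment over the family of pairs.
#'
#' @param data Data frame with columns `subject`, `condition`, `value` (one
#'   value per cell). Subjects with missing cells are dropped listwise with a
#'   message.
#' @param measure Label copied into the result rows.
#' @param alpha Significance level.
#' @return List: `omnibus` (one-row result), `posthoc` (data frame of
#'   pairwise contrasts, or `NULL` when the omnibus is not significant).
#' @export
position_anova <- function(data, measure = "value", alpha = 0.05) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  conds <- unique(data$condition)
  if (length(conds) < 2) stop("position_anova needs >= 2 conditions")
  counts <- table(data$subject, data$condition)
  complete <- rownames(counts)[apply(counts == 1, 1, all)]
  if (length(complete) < nrow(counts))
    message(sprintf("position_anova(%s): dropped %d subject(s) with missing cells [LISTWISE_DROP]",
                    measure, nrow(counts) - length(complete)))
  if (length(complete) < 2) stop("position_anova needs >= 2 complete subjects")
  d <- data[data$subject %in% complete, , drop = FALSE]
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)

  fit <- stats::aov(value ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  if (!is.finite(tab["Residuals", "Mean Sq"]) ||
      tab["Residuals", "Mean Sq"] <= .Machine$double.eps * mean(d$value^2))
    stop("degenerate data: zero residual variance in position ANOVA")
  f <- tab["condition", "F value"]
  p <- tab["condition", "Pr(>F)"]
  omnibus <- stats_result("rm_anova", f, tab["condition", "Df"],
                          tab["Residuals", "Df"], p,
                          contrast = paste0(measure, ": position omnibus"),
                          alpha = alpha)
  posthoc <- NULL
  if (p < alpha) {
    pairs <- utils::combn(levels(d$condition), 2)
    m <- ncol(pairs)
    rows <- lapply(seq_len(m), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      da <- d$value[d$condition == a][order(d$subject[d$condition == a])]
      db <- d$value[d$condition == b][order(d$subject[d$condition == b])]
      tt <- stats::t.test(da, db, paired = TRUE)
      stats_result("paired_t", unname(tt$statistic), unname(tt$parameter),
                   p_value = tt$p.value,
                   adjusted_p = bonferroni(tt$p.value, m),
                   contrast = paste0(measure, ": ", a, " vs ", b),
                   alpha = alpha)
    })
    posthoc <- do.call(rbind, rows)
  }
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Two-sided paired t-test
#'
#' @param pre,post Matched per-subject values.
#' @param measure Label for the contrast description.
#' @param alpha Significance level.
#' @return One-row result data frame.
#' @export
paired_ttest <- function(pre, post, measure = "value", alpha = 0.05) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  dd <- post - pre
  if (stats::sd(dd) == 0)
    stop("degenerate data: zero variance of paired differences")
  tt <- stats::t.test(post, pre, paired = TRUE)
  stats_result("paired_t", unname(tt$statistic), unname(tt$parameter),
               p_value = tt$p.value,
               contrast = paste0(measure, ": post vs pre"), alpha = alpha)
}

#' Two-sided independent-samples t-test
#'
#' Equal-variance (pooled) form by default, matching classical usage; Welch's
#' correction behind the `welch` flag.
#'
#' @param a,b Group samples (each n >= 2).
#' @param measure Label for the contrast description.
#' @param welch Use the Welch unequal-variance form.
#' @param alpha Significance level.
#' @return One-row result data frame.
#' @export
independent_ttest <- function(a, b, measure = "value", welch = FALSE,
                              alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a, b)) == 0)
    stop("degenerate data: zero variance in both groups")
  tt <- stats::t.test(a, b, var.equal = !welch)
  stats_result(if (welch) "welch_t" else "independent_t",
               unname(tt$statistic), unname(tt$parameter),
               p_value = tt$p.value,
               contrast = paste0(measure, ": group a vs b"), alpha = alpha)
}

#' Percent change from pre to post
#'
#' `(i2 - i1) / i1 * 100`; undefined when the pre value is zero.
#'
#' @param i1 Pre value (nonzero).
#' @param i2 Post value.
#' @return List: `i1`, `i2`, `pct`.
#' @export
percent_change <- function(i1, i2) {
  if (any(i1 == 0)) stop("percent change undefined for a zero pre value")
  list(i1 = i1, i2 = i2, pct = (i2 - i1) / i1 * 100)
}

#' Signed latency-change table
#'
#' Per-subject, per-muscle signed change in onset latency (ms) from pre to
#' post, plus the +/- sign grid (muscles as rows, subjects as columns) used
#' to display the variability of latency changes.
#'
#' @param pre,post Data frames with columns `subject_id`, `muscle`,
#'   `onset_ms`, matched on (subject, muscle). Unmatched keys are an error
#'   naming them.
#' @return Data frame with `subject_id`, `muscle`, `pre_ms`, `post_ms`,
#'   `change_ms`, `sign` (`"+"`, `"-"` or `"0"`); the sign grid is attached
#'   as `attr(, "sign_grid")`.
#' @export
latency_change_table <- function(pre, post) {
  need <- c("subject_id", "muscle", "onset_ms")
  stopifnot(all(need %in% names(pre)), all(need %in% names(post)))
  key <- function(d) paste(d$subject_id, d$muscle, sep = ":")
  only_pre <- setdiff(key(pre), key(post))
  only_post <- setdiff(key(post), key(pre))
  if (length(only_pre) || length(only_post))
    stop("unmatched (subject, muscle) keys: ",
         paste(c(only_pre, only_post), collapse = ", "))
  m <- merge(pre[need], post[need], by = c("subject_id", "muscle"),
             suffixes = c("_pre", "_post"))
  out <- data.frame(subject_id = m$subject_id, muscle = m$muscle,
                    pre_ms = m$onset_ms_pre, post_ms = m$onset_ms_post,
                    change_ms = m$onset_ms_post - m$onset_ms_pre,
                    stringsAsFactors = FALSE)
  out$sign <- ifelse(out$change_ms > 0, "+",
                     ifelse(out$change_ms < 0, "-", "0"))
  out <- out[order(out$muscle, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  grid <- stats::xtabs(~ muscle + subject_id, data = out)  # shape template
  grid[] <- NA_character_
  for (i in seq_len(nrow(out)))
    grid[out$muscle[i], out$subject_id[i]] <- out$sign[i]
  attr(out, "sign_grid") <- grid
  out
}

#' Unwrap angular values onto a continuous branch
#'
#' Directions entering linear statistics (t-tests, ANOVA) are mapped into the
#' 360-degree branch centred on their circular mean, so a cluster straddling
#' the +/-180 boundary is not split.
#'
#' @param deg Directions in degrees.
#' @return Unwrapped directions (degrees, possibly outside `(-180, 180]`).
#' @export
unwrap_directions <- function(deg) {
  ctr <- circular_mean_deg(deg)
  if (!is.finite(ctr)) return(deg)
  ((deg - ctr + 180) %% 360) - 180 + ctr
}
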