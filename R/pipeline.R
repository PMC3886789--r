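## End-to-end orchestration of the two tasks:
##   segment -> preprocess -> detect -> quantify -> summarize -> statistics.
## Deterministic given inputs and configuration; the effective configuration
## is written next to the outputs so a run can be reproduced from them.

#' Analysis pipeline configuration
#'
#' @param threshold_k Onset threshold multiplier (baseline SDs).
#' @param baseline_ms Pre-stimulus baseline window `[start, end)` in ms.
#' @param offset_ms Response offset (end of the reflex analysis window) in ms
#'   after the stimulus. The offset criterion of the source recordings is a
#'   free parameter; 200 ms matches the reflex analysis window.
#' @param min_above_ms Debounce: minimum time above threshold; 0 reproduces
#'   the bare first-crossing rule.
#' @param blank_ms Artifact blanking after the stimulus (0 = off).
#' @param force_window_ms Force-peak window: 200 for reflex trials, 350 for
#'   practice trials.
#' @param simultaneous_peak Read Fx/Fy at the single time of maximal planar
#'   norm instead of independent per-axis peaks.
#' @param alpha Significance level.
#' @param seed Seed for any resampling (stored for provenance).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_k = 3, baseline_ms = c(-100, 0),
                            offset_ms = 200, min_above_ms = 2, blank_ms = 0,
                            force_window_ms = 200, simultaneous_peak = FALSE,
                            alpha = 0.05, seed = NULL) {
  stopifnot(threshold_k > 0, offset_ms > 0, force_window_ms > 0,
            min_above_ms >= 0, blank_ms >= 0, alpha > 0, alpha < 1)
  structure(list(threshold_k = threshold_k, baseline_ms = baseline_ms,
                 offset_ms = offset_ms, min_above_ms = min_above_ms,
                 blank_ms = blank_ms, force_window_ms = force_window_ms,
                 simultaneous_peak = simultaneous_peak, alpha = alpha,
                 seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

## Resolve an input that may be a synthetic_experiment, a list of recordings,
## or a directory of bundle subdirectories.
#' @noRd
resolve_recordings <- function(input) {
  if (inherits(input, "synthetic_experiment")) return(input$recordings)
  if (inherits(input, "nwr_recording")) return(list(input))
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    dirs <- list.dirs(input, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "layout.json"))]
    if (!length(dirs)) stop("no recording bundles found under ", input)
    return(lapply(dirs, read_recording))
  }
  if (is.list(input)) return(input)
  stop("cannot interpret input recordings")
}

#' Process one recording into per-trial and summary tables
#'
#' Segments the recording, runs the EMG reflex chain on every EMG channel and
#' the force-vector analysis on every epoch, and averages across trials.
#'
#' @param recording An `nwr_recording`.
#' @param config A [pipeline_config()].
#' @return List: `emg_trials`, `force_trials` (per-trial rows),
#'   `emg_summary` (per muscle), `force_summary` (one row).
#' @export
process_recording <- function(recording, config = pipeline_config()) {
  pre <- -config$baseline_ms[1]
  post <- max(config$offset_ms, config$force_window_ms, 350)
  epochs <- segment_trials(recording, pre_ms = pre, post_ms = post)
  if (!length(epochs)) stop("no usable epochs in recording")
  muscles <- intersect(EMG_CHANNELS, names(recording$channels))
  nk <- length(epochs) * length(muscles)
  trial_v <- integer(nk); mus_v <- character(nk)
  onset_v <- amp_v <- thr_v <- numeric(nk)
  k <- 0L
  for (ep in epochs) for (m in muscles) {
    k <- k + 1L
    meas <- reflex_measures(ep$channels[[m]], config)
    trial_v[k] <- ep$trial; mus_v[k] <- m
    onset_v[k] <- meas$onset_ms; amp_v[k] <- meas$mean_emg
    thr_v[k] <- meas$threshold
  }
  emg <- if (nk) data.frame(trial = trial_v, muscle = mus_v,
                            onset_ms = onset_v, offset_ms = config$offset_ms,
                            mean_emg = amp_v, threshold = thr_v,
                            stringsAsFactors = FALSE) else NULL
  force <- NULL
  if (all(c("Fx", "Fy") %in% names(recording$channels)))
    force <- do.call(rbind, lapply(epochs, analyze_force_trial,
                                   config = config))
  sid <- recording$layout$subject_id
  cond <- recording$layout$condition
  list(emg_trials = emg, force_trials = force,
       emg_summary = if (!is.null(emg))
         summarize_condition(emg, sid, cond) else NULL,
       force_summary = if (!is.null(force))
         force_condition_summary(force, sid, cond) else NULL)
}

## Stack per-recording summaries over an experiment.
#' @noRd
summarize_experiment <- function(recordings, config) {
  emg <- list(); force <- list()
  for (rec in recordings) {
    res <- process_recording(rec, config)
    emg[[length(emg) + 1L]] <- res$emg_summary
    force[[length(force) + 1L]] <- res$force_summary
  }
  list(emg_summary = do.call(rbind, emg),
       force_summary = do.call(rbind, force))
}

## Long (subject, condition, value) frame for one force measure, with
## directions unwrapped onto a continuous branch.
#' @noRd
force_measure_frame <- function(fs, measure) {
  v <- fs[[measure]]
  if (measure == "direction_deg") v <- unwrap_directions(v)
  data.frame(subject = fs$subject_id, condition = fs$condition, value = v,
             stringsAsFactors = FALSE)
}

FORCE_MEASURES <- c("peak_fx_n", "peak_fy_n", "peak_mx_nm", "peak_my_nm",
                    "magnitude_n", "direction_deg")

#' Run the joint-position task analysis
#'
#' Per muscle, onset latency and mean-EMG amplitude are compared across the
#' five static positions with repeated-measures ANOVAs (subject as the random
#' factor, Bonferroni-adjusted pairwise post hocs when the omnibus is
#' significant); the same omnibus is run for each force measure (per-axis
#' peaks, moments, vector magnitude and direction). The repeated neutral
#' position is excluded from the omnibus and compared against the initial
#' neutral with independent t-tests as the habituation check; if it is
#' missing the check is skipped with a warning.
#'
#' @param input A `synthetic_experiment`, a list of `nwr_recording`s, or a
#'   directory of bundles.
#' @param config A [pipeline_config()].
#' @param out_dir If given, `emg_summary.csv`, `force_summary.csv`,
#'   `stats.csv` and `config.yaml` are written there.
#' @return List: `emg_summary`, `force_summary`, `stats`.
#' @export
run_position_task <- function(input, config = pipeline_config(),
                              out_dir = NULL) {
  recs <- resolve_recordings(input)
  sums <- summarize_experiment(recs, config)
  es <- sums$emg_summary
  fs <- sums$force_summary
  positions <- setdiff(unique(es$condition), "NEUT_REPEAT")
  if (length(positions) < 2) stop("need bundles for >= 2 positions")
  stats_rows <- list()
  add <- function(x) stats_rows[[length(stats_rows) + 1L]] <<- x

  for (mus in unique(es$muscle)) {
    dm <- es[es$muscle == mus & es$condition %in% positions, ]
    for (meas in c("onset_mean_ms", "amp_mean")) {
      d <- data.frame(subject = dm$subject_id, condition = dm$condition,
                      value = dm[[meas]])
      lbl <- paste0(mus, ":", sub("_mean.*", "", meas))
      if (sum(is.finite(d$value)) < 4 ||
          length(unique(d$condition[is.finite(d$value)])) < 2) next
      res <- tryCatch(position_anova(d, measure = lbl, alpha = config$alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      add(res$omnibus)
      if (!is.null(res$posthoc)) add(res$posthoc)
    }
  }
  if (!is.null(fs)) {
    fsp <- fs[fs$condition %in% positions, ]
    for (meas in FORCE_MEASURES) {
      res <- tryCatch(position_anova(force_measure_frame(fsp, meas),
                                     measure = paste0("force:", meas),
                                     alpha = config$alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      add(res$omnibus)
      if (!is.null(res$posthoc)) add(res$posthoc)
    }
  }

  # habituation: initial vs repeated neutral, independent t-tests
  if (!"NEUT_REPEAT" %in% es$condition) {
    warning("NEUT_REPEAT bundles missing: habituation check skipped [NO_HABITUATION]",
            call. = FALSE)
  } else {
    for (mus in unique(es$muscle)) {
      for (meas in c("onset_mean_ms", "amp_mean")) {
        a <- es[es$muscle == mus & es$condition == "NEUT", meas]
        b <- es[es$muscle == mus & es$condition == "NEUT_REPEAT", meas]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2 || length(b) < 2) next
        r <- tryCatch(independent_ttest(a, b, alpha = config$alpha),
                      error = function(e) NULL)
        if (is.null(r)) next
        r$contrast <- paste0(mus, ":", sub("_mean.*", "", meas),
                             ": NEUT vs NEUT_REPEAT")
        add(r)
      }
    }
    if (!is.null(fs)) {
      for (meas in FORCE_MEASURES) {
        a <- fs[fs$condition == "NEUT", meas]
        b <- fs[fs$condition == "NEUT_REPEAT", meas]
        if (meas == "direction_deg") {
          u <- unwrap_directions(c(a, b))
          a <- u[seq_along(a)]; b <- u[-seq_along(a)]
        }
        if (length(a) < 2 || length(b) < 2) next
        r <- tryCatch(independent_ttest(a, b, alpha = config$alpha),
                      error = function(e) NULL)
        if (is.null(r)) next
        r$contrast <- paste0("force:", meas, ": NEUT vs NEUT_REPEAT")
        add(r)
      }
    }
  }

  out <- list(emg_summary = es, force_summary = fs,
              stats = do.call(rbind, stats_rows))
  if (!is.null(out_dir)) {
    write_results(out, out_dir)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

## Matched pre/post vectors for one measure over common subjects.
#' @noRd
paired_frames <- function(s_pre, s_post, meas) {
  common <- intersect(s_pre$subject_id, s_post$subject_id)
  pre <- s_pre[match(common, s_pre$subject_id), meas]
  post <- s_post[match(common, s_post$subject_id), meas]
  keep <- is.finite(pre) & is.finite(post)
  list(pre = pre[keep], post = post[keep], subjects = common[keep])
}

#' Run the conditioning (motor practice) task analysis
#'
#' For each practice type (EXT, FLEX) with both pre and post bundles: paired
#' t-tests on every per-muscle measure (onset latency, mean EMG) and every
#' force measure before vs after practice. Between practice types, percent
#' changes of amplitudes and force measures (and the absolute latency change
#' in ms) are compared with independent t-tests. Also returns the signed
#' per-subject latency-change tables with their +/- sign grids. If only one
#' practice type is present the between-condition stage is skipped with a
#' warning.
#'
#' @inheritParams run_position_task
#' @return List: `emg_summary`, `force_summary`, `stats`,
#'   `latency_changes` (named per practice type), `percent_changes`.
#' @export
run_conditioning_task <- function(input, config = pipeline_config(),
                                  out_dir = NULL) {
  recs <- resolve_recordings(input)
  sums <- summarize_experiment(recs, config)
  es <- sums$emg_summary
  fs <- sums$force_summary
  stats_rows <- list()
  add <- function(x) stats_rows[[length(stats_rows) + 1L]] <<- x
  practiced <- intersect(c("EXT", "FLEX"),
                         unique(sub("_(PRE|POST)$", "", es$condition)))
  have_both <- vapply(practiced, function(p)
    all(paste0(p, c("_PRE", "_POST")) %in% es$condition), logical(1))
  practiced <- practiced[have_both]
  if (!length(practiced)) stop("need PRE and POST bundles for at least one practice type")

  latency_changes <- list()
  pct <- list()  # long rows: practice, subject, measure, value

  for (p in practiced) {
    pre_lab <- paste0(p, "_PRE"); post_lab <- paste0(p, "_POST")
    for (mus in unique(es$muscle)) {
      s_pre <- es[es$condition == pre_lab & es$muscle == mus, ]
      s_post <- es[es$condition == post_lab & es$muscle == mus, ]
      for (meas in c("onset_mean_ms", "amp_mean")) {
        pp <- paired_frames(s_pre, s_post, meas)
        if (length(pp$pre) < 2) next
        r <- tryCatch(paired_ttest(pp$pre, pp$post, alpha = config$alpha),
                      error = function(e) NULL)
        if (is.null(r)) next
        r$contrast <- paste0(p, ":", mus, ":", sub("_mean.*", "", meas),
                             ": post vs pre")
        add(r)
        if (meas == "amp_mean") {
          ok <- pp$pre != 0
          pct[[length(pct) + 1L]] <- data.frame(
            practice = p, subject = pp$subjects[ok],
            measure = paste0(mus, ":amp"),
            value = percent_change(pp$pre[ok], pp$post[ok])$pct)
        } else {
          pct[[length(pct) + 1L]] <- data.frame(
            practice = p, subject = pp$subjects,
            measure = paste0(mus, ":onset_change_ms"),
            value = pp$post - pp$pre)
        }
      }
    }
    # signed latency-change table (Table-style muscles x subjects grid)
    pre_df <- es[es$condition == pre_lab,
                 c("subject_id", "muscle", "onset_mean_ms")]
    post_df <- es[es$condition == post_lab,
                  c("subject_id", "muscle", "onset_mean_ms")]
    names(pre_df)[3] <- names(post_df)[3] <- "onset_ms"
    pre_df <- pre_df[stats::complete.cases(pre_df), ]
    post_df <- post_df[stats::complete.cases(post_df), ]
    keys <- intersect(paste(pre_df$subject_id, pre_df$muscle),
                      paste(post_df$subject_id, post_df$muscle))
    pre_df <- pre_df[paste(pre_df$subject_id, pre_df$muscle) %in% keys, ]
    post_df <- post_df[paste(post_df$subject_id, post_df$muscle) %in% keys, ]
    latency_changes[[p]] <- latency_change_table(pre_df, post_df)

    if (!is.null(fs)) {
      s_pre <- fs[fs$condition == pre_lab, ]
      s_post <- fs[fs$condition == post_lab, ]
      for (meas in FORCE_MEASURES) {
        if (meas == "direction_deg") {
          u <- unwrap_directions(c(s_pre[[meas]], s_post[[meas]]))
          s_pre[[meas]] <- u[seq_len(nrow(s_pre))]
          s_post[[meas]] <- u[-seq_len(nrow(s_pre))]
        }
        pp <- paired_frames(s_pre, s_post, meas)
        if (length(pp$pre) < 2) next
        r <- tryCatch(paired_ttest(pp$pre, pp$post, alpha = config$alpha),
                      error = function(e) NULL)
        if (is.null(r)) next
        r$contrast <- paste0(p, ":force:", meas, ": post vs pre")
        add(r)
        ok <- pp$pre != 0
        pct[[length(pct) + 1L]] <- data.frame(
          practice = p, subject = pp$subjects[ok],
          measure = paste0("force:", meas),
          value = percent_change(pp$pre[ok], pp$post[ok])$pct)
      }
    }
  }

  pct <- if (length(pct)) do.call(rbind, pct) else NULL
  if (length(practiced) < 2) {
    warning("only one practice type present: EXT vs FLEX comparison skipped [NO_BETWEEN]",
            call. = FALSE)
  } else if (!is.null(pct)) {
    for (meas in unique(pct$measure)) {
      a <- pct$value[pct$practice == "EXT" & pct$measure == meas]
      b <- pct$value[pct$practice == "FLEX" & pct$measure == meas]
      if (length(a) < 2 || length(b) < 2) next
      r <- tryCatch(independent_ttest(a, b, alpha = config$alpha),
                    error = function(e) NULL)
      if (is.null(r)) next
      r$contrast <- paste0(meas, ": EXT vs FLEX")
      add(r)
    }
  }

  out <- list(emg_summary = es, force_summary = fs,
              stats = do.call(rbind, stats_rows),
              latency_changes = latency_changes, percent_changes = pct)
  if (!is.null(out_dir)) {
    write_results(out, out_dir)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}
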