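# Independent oracles and small fixture builders shared across test files.
# The oracles deliberately use naive exhaustive loops, not the package's
# vectorized code paths.

# Build a rectified-tagged segment directly from sample values (>= 0).
make_rect_segment <- function(samples, rate, i0, name = "X") {
  seg <- channel_segment(samples, rate, i0, name)
  attr(seg, "rectified") <- TRUE
  seg
}

# Exhaustive per-sample onset scan: first sample with relative time in
# (start, end] such that every sample in the closed span [t, t + min_above]
# exceeds the threshold. Mirrors the detection contract with plain loops.
scan_onset_oracle <- function(seg, threshold, search_ms = c(0, 200),
                              min_above_ms = 2, blank_ms = 0) {
  t_ms <- segment_times_ms(seg)
  n_min <- as.integer(floor(min_above_ms * seg$rate / 1000 + 1e-9)) + 1L
  lo <- max(search_ms[1], blank_ms)
  for (i in seq_along(t_ms)) {
    if (t_ms[i] <= lo + 1e-9 || t_ms[i] > search_ms[2] + 1e-9) next
    if (i + n_min - 1L > length(t_ms)) next
    run_ok <- TRUE
    for (j in i:(i + n_min - 1L)) {
      if (!(seg$samples[j] > threshold)) { run_ok <- FALSE; break }
    }
    if (run_ok) return(t_ms[i])
  }
  NA_real_
}

# Exhaustive extremum scan for a baseline-corrected force axis.
scan_peak_oracle <- function(seg, window_ms, expected_sign,
                             baseline_ms = c(-100, 0)) {
  t_ms <- segment_times_ms(seg)
  b <- seg$samples[t_ms >= baseline_ms[1] - 1e-9 & t_ms < baseline_ms[2] - 1e-9]
  x <- seg$samples - mean(b)
  best <- NULL
  for (i in seq_along(t_ms)) {
    if (t_ms[i] <= 1e-9 || t_ms[i] > window_ms + 1e-9) next
    if (is.null(best) ||
        (expected_sign > 0 && x[i] > x[best]) ||
        (expected_sign < 0 && x[i] < x[best])) best <- i
  }
  list(value = x[best], time_ms = t_ms[best])
}

# Textbook repeated-measures ANOVA from sums of squares, on a subjects x
# conditions value matrix.
rm_anova_oracle <- function(m) {
  s <- nrow(m); c <- ncol(m)
  gm <- mean(m)
  ss_cond <- s * sum((colMeans(m) - gm)^2)
  ss_subj <- c * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1; df2 <- (c - 1) * (s - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Reduced-size synthetic spec for fast tests; defaults stay the study
# conditions, only the problem size shrinks.
test_spec <- function(seed = 1, n_subjects = 3, n_trials = 2,
                      emg_rate = 500, ...) {
  synthetic_spec(seed = seed, n_subjects = n_subjects, n_trials = n_trials,
                 emg_rate = emg_rate, ...)
}

# Run the analysis chain on one gen_emg_trial epoch; returns detected onset.
detect_on_trial <- function(trial, config = pipeline_config()) {
  r <- rectify(remove_dc(trial$segment))
  b <- baseline_stats(r, config$baseline_ms)
  detect_onset(r, b, search_ms = c(0, config$offset_ms),
               min_above_ms = config$min_above_ms, k = config$threshold_k,
               blank_ms = config$blank_ms)$onset_ms
}
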