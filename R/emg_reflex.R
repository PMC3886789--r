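## Reflex EMG chain: DC removal -> rectification -> baseline statistics ->
## threshold onset detection -> onset-to-offset mean EMG -> trial averaging.
##
## The detector implements the classic rule: the reflex onset is the first
## post-stimulus sample at which the rectified EMG exceeds the baseline mean
## plus k standard deviations (k = 3 by default) and stays above that
## threshold for at least `min_above_ms`. Baseline statistics come from the
## 100 ms immediately preceding the stimulus.

#' Remove the DC offset of a segment
#'
#' Subtracts the full-epoch mean so the output averages to zero. DC removal
#' precedes any windowing or rectification in the processing chain.
#'
#' @param seg A [channel_segment()].
#' @return The segment with zero-mean samples.
#' @export
remove_dc <- function(seg) {
  stopifnot(inherits(seg, "channel_segment"))
  seg$samples <- seg$samples - mean(seg$samples)
  seg
}

#' Full-wave rectify a segment
#'
#' Elementwise absolute value. The result is tagged so that downstream
#' baseline/onset operations can enforce the processing order.
#'
#' @param seg A [channel_segment()] (DC already removed by pipeline order).
#' @return The segment with non-negative samples.
#' @export
rectify <- function(seg) {
  stopifnot(inherits(seg, "channel_segment"))
  seg$samples <- abs(seg$samples)
  attr(seg, "rectified") <- TRUE
  seg
}

#' @noRd
assert_rectified <- function(seg, op) {
  if (!isTRUE(attr(seg, "rectified")))
    stop(op, "() expects a rectified segment; apply rectify(remove_dc(x)) first")
}

#' Baseline statistics of the rectified pre-stimulus window
#'
#' @param seg Rectified [channel_segment()].
#' @param window_ms Length-2 window `[start, end)` in ms relative to the
#'   stimulus; the end must be at or before 0. Default the 100 ms pre-stimulus
#'   window `c(-100, 0)`.
#' @return List of class `baseline_stats`: `mean`, `sd` (sample SD, n-1
#'   denominator), `n`, `window_ms`.
#' @export
baseline_stats <- function(seg, window_ms = c(-100, 0)) {
  assert_rectified(seg, "baseline_stats")
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2],
            window_ms[2] <= 0)
  idx <- window_idx(seg, window_ms[1], window_ms[2])
  if (!length(idx) || idx[1] < 1 || min(segment_times_ms(seg)) > window_ms[1] + 1e-9)
    stop("baseline window [", window_ms[1], ", ", window_ms[2],
         ") not covered by the epoch")
  x <- seg$samples[idx]
  structure(list(mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x), window_ms = window_ms),
            class = "baseline_stats")
}

#' Detect the reflex onset by sustained threshold crossing
#'
#' Returns the time of the first sample inside the search window at which the
#' rectified EMG exceeds `baseline$mean + k * baseline$sd` and remains above
#' it throughout the closed interval `[t, t + min_above_ms]` (every sample in
#' that span must exceed the threshold, so the rule debounces isolated spikes
#' at any sampling rate). `min_above_ms = 0` reproduces the bare
#' first-crossing rule.
#' Onsets are reported at sample resolution (no sub-sample interpolation).
#'
#' @param seg Rectified [channel_segment()].
#' @param baseline [baseline_stats()] of the same segment.
#' @param search_ms Length-2 search window `(start, end]` in ms after the
#'   stimulus; default `c(0, 200)`, the reflex analysis window.
#' @param min_above_ms Minimum time the signal must stay above threshold.
#' @param k Threshold multiplier (default 3 SDs).
#' @param blank_ms Optional artifact blanking: samples in `(0, blank_ms]` are
#'   excluded from the search (default 0, off).
#' @return List of class `onset_detection`: `onset_ms` (`NA` if no qualifying
#'   crossing), `threshold`, and `index` into the segment.
#' @export
detect_onset <- function(seg, baseline, search_ms = c(0, 200),
                         min_above_ms = 2, k = 3, blank_ms = 0) {
  assert_rectified(seg, "detect_onset")
  stopifnot(inherits(baseline, "baseline_stats"),
            length(search_ms) == 2, search_ms[1] >= 0,
            search_ms[2] > search_ms[1], min_above_ms >= 0, blank_ms >= 0)
  threshold <- baseline$mean + k * baseline$sd
  if (baseline$sd == 0 && baseline$mean == 0) {
    warning("degenerate baseline (mean 0, sd 0); detecting against threshold 0 [DEGENERATE_BASELINE]",
            call. = FALSE)
    threshold <- 0
  }
  t_ms <- segment_times_ms(seg)
  lo <- max(search_ms[1], blank_ms)
  cand <- which(t_ms > lo + 1e-9 & t_ms <= search_ms[2] + 1e-9)
  res <- list(onset_ms = NA_real_, threshold = threshold, index = NA_integer_)
  class(res) <- "onset_detection"
  if (!length(cand)) return(res)
  # samples observed in [t, t + min_above_ms]: floor(.) + 1
  n_min <- as.integer(floor(min_above_ms * seg$rate / 1000 + 1e-9)) + 1L
  above <- seg$samples[cand] > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n_min)
  if (!length(ok)) return(res)
  i <- cand[starts[ok[1]]]
  res$onset_ms <- t_ms[i]
  res$index <- i
  res
}

#' Mean rectified EMG between onset and offset
#'
#' Arithmetic mean of the rectified samples with relative time in
#' `[onset_ms, offset_ms)` (closed at onset, open at offset).
#'
#' @param seg Rectified [channel_segment()].
#' @param onset_ms Detected onset (ms); `NA` propagates to an `NA` result.
#' @param offset_ms Response end (ms); the default analysis uses 200 ms after
#'   the stimulus.
#' @return Mean rectified amplitude, or `NA_real_` if `onset_ms` is `NA`.
#' @export
quantify_response <- function(seg, onset_ms, offset_ms) {
  assert_rectified(seg, "quantify_response")
  if (is.na(onset_ms)) return(NA_real_)
  stopifnot(onset_ms <= offset_ms)
  idx <- window_idx(seg, onset_ms, offset_ms)
  if (!length(idx)) stop("empty response window [", onset_ms, ", ",
                         offset_ms, ")")
  mean(seg$samples[idx])
}

#' Analyze one muscle in one epoch
#'
#' Runs the full chain (DC removal, rectification, baseline, onset detection,
#' response quantification) on one channel of a [segment_trials()] epoch.
#'
#' @param epoch A `trial_epoch`.
#' @param muscle Channel name.
#' @param config Analysis configuration from [pipeline_config()].
#' @return One-row data frame: `trial`, `muscle`, `onset_ms`, `offset_ms`,
#'   `mean_emg`, `threshold`.
#' @export
analyze_reflex_trial <- function(epoch, muscle, config = pipeline_config()) {
  seg <- epoch$channels[[muscle]]
  if (is.null(seg)) stop("epoch has no channel '", muscle, "'")
  m <- reflex_measures(seg, config)
  data.frame(trial = epoch$trial, muscle = muscle,
             onset_ms = m$onset_ms, offset_ms = config$offset_ms,
             mean_emg = m$mean_emg, threshold = m$threshold,
             stringsAsFactors = FALSE)
}

## Shared chain for one segment: preprocess, detect, quantify.
#' @noRd
reflex_measures <- function(seg, config) {
  r <- rectify(remove_dc(seg))
  b <- baseline_stats(r, config$baseline_ms)
  det <- detect_onset(r, b, search_ms = c(0, config$offset_ms),
                      min_above_ms = config$min_above_ms,
                      k = config$threshold_k, blank_ms = config$blank_ms)
  # an onset at the very end of the search window leaves no response window
  amp <- if (!is.na(det$onset_ms) && det$onset_ms < config$offset_ms)
    quantify_response(r, det$onset_ms, config$offset_ms) else NA_real_
  list(onset_ms = det$onset_ms, mean_emg = amp, threshold = det$threshold)
}

#' Average reflex responses over the trials of one condition
#'
#' Per muscle, the mean and SD of onset latency and mean-EMG amplitude over
#' the trials with a detected onset; trials without a detection are excluded
#' and counted. Muscles with zero detections (typically the erector spinae)
#' come out with `NA` summaries and `n_trials_used = 0`.
#'
#' @param responses Data frame of per-trial rows as returned by
#'   [analyze_reflex_trial()] (columns `trial`, `muscle`, `onset_ms`,
#'   `mean_emg`).
#' @param subject_id,condition Identifiers copied into the summary.
#' @return Data frame, one row per muscle: onset/amplitude means and SDs,
#'   `n_trials_used`, `n_trials`.
#' @export
summarize_condition <- function(responses, subject_id = NA, condition = NA) {
  if (is.null(responses) || nrow(responses) == 0L)
    stop("summarize_condition: empty response table")
  out <- lapply(split(responses, responses$muscle), function(d) {
    det <- d[!is.na(d$onset_ms), , drop = FALSE]
    n_used <- nrow(det)
    data.frame(subject_id = subject_id, condition = condition,
               muscle = d$muscle[1],
               onset_mean_ms = if (n_used) mean(det$onset_ms) else NA_real_,
               onset_sd_ms = if (n_used > 1) stats::sd(det$onset_ms) else
                 (if (n_used == 1) 0 else NA_real_),
               amp_mean = if (n_used) mean(det$mean_emg) else NA_real_,
               amp_sd = if (n_used > 1) stats::sd(det$mean_emg) else
                 (if (n_used == 1) 0 else NA_real_),
               n_trials_used = n_used, n_trials = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
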