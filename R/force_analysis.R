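## Endpoint force/moment analysis in the horizontal (X-Y) plane.
##
## Each trial yields per-axis local peaks of the baseline-corrected traces in
## the post-stimulus window, and the planar resultant vector from the peak Fx
## (+x, lateral) and peak Fy (-y, posterior toward the subject). Fz and Mz
## are never analyzed: with the limb supported they mostly carry slowly
## varying gravitational load that changes with arm position.

#' Signed local peak of a force/moment axis
#'
#' Baseline-corrects the trace by subtracting its mean over the pre-stimulus
#' window, then returns the in-window extremum in the expected direction
#' (maximum for `+1`, minimum for `-1`) with its time. If the extremum has
#' the opposite sign (no response in the expected direction) it is returned
#' unchanged with `sign_matches = FALSE`.
#'
#' @param seg A [channel_segment()] of a force or moment channel.
#' @param window_ms Post-stimulus window length in ms; the search spans
#'   `(0, window_ms]`. 200 for reflex trials, 350 for practice trials.
#' @param expected_sign `+1` or `-1`.
#' @param baseline_ms Pre-stimulus window for baseline correction.
#' @return List: `value` (signed, baseline-corrected), `time_ms`,
#'   `sign_matches`.
#' @export
peak_axis <- function(seg, window_ms = 200, expected_sign = 1,
                      baseline_ms = c(-100, 0)) {
  stopifnot(inherits(seg, "channel_segment"), window_ms > 0,
            expected_sign %in% c(-1, 1))
  bidx <- window_idx(seg, baseline_ms[1], baseline_ms[2])
  if (!length(bidx)) stop("baseline window not covered by the epoch")
  x <- seg$samples - mean(seg$samples[bidx])
  t_ms <- segment_times_ms(seg)
  idx <- which(t_ms > 1e-9 & t_ms <= window_ms + 1e-9)
  if (!length(idx)) stop("empty post-stimulus window")
  i <- if (expected_sign > 0) idx[which.max(x[idx])] else idx[which.min(x[idx])]
  v <- x[i]
  list(value = v, time_ms = t_ms[i],
       sign_matches = (v == 0) || (sign(v) == expected_sign))
}

#' Planar resultant force vector from per-axis peaks
#'
#' @param peak_fx,peak_fy Signed peak forces (N). The stereotyped withdrawal
#'   is posterior-lateral, i.e. `peak_fx > 0`, `peak_fy < 0` (fourth
#'   quadrant).
#' @return List: `magnitude` (Euclidean norm, N) and `direction_deg`
#'   (degrees counterclockwise from +X, in `(-180, 180]`; `NA` when both
#'   peaks are zero).
#' @export
resultant_vector <- function(peak_fx, peak_fy) {
  stopifnot(is.finite(peak_fx), is.finite(peak_fy))
  mag <- sqrt(peak_fx^2 + peak_fy^2)
  dir <- if (mag == 0) NA_real_ else atan2(peak_fy, peak_fx) * 180 / pi
  list(magnitude = mag, direction_deg = dir)
}

#' Analyze the endpoint force response of one epoch
#'
#' Extracts peak Fx (expected +), peak Fy (expected -), peak Mx and My (by
#' largest absolute deflection, sign retained), and the planar resultant.
#' With `simultaneous_peak = TRUE` the Fx/Fy pair is instead read off at the
#' single time maximizing the planar norm of the baseline-corrected (Fx, Fy)
#' trace; by default the two axes peak independently.
#'
#' @param epoch A `trial_epoch` containing `Fx`, `Fy` and optionally
#'   `Mx`, `My`.
#' @param config [pipeline_config()]; uses `force_window_ms`,
#'   `simultaneous_peak`, `baseline_ms`.
#' @return One-row data frame: `trial`, `peak_fx_n`, `peak_fy_n`,
#'   `peak_mx_nm`, `peak_my_nm`, `magnitude_n`, `direction_deg`,
#'   `fx_sign_ok`, `fy_sign_ok`.
#' @export
analyze_force_trial <- function(epoch, config = pipeline_config()) {
  fx <- epoch$channels[["Fx"]]
  fy <- epoch$channels[["Fy"]]
  if (is.null(fx) || is.null(fy))
    stop("epoch must contain Fx and Fy channels")
  w <- config$force_window_ms
  if (isTRUE(config$simultaneous_peak)) {
    bidx <- window_idx(fx, config$baseline_ms[1], config$baseline_ms[2])
    xs <- fx$samples - mean(fx$samples[bidx])
    ys <- fy$samples - mean(fy$samples[window_idx(fy, config$baseline_ms[1],
                                                  config$baseline_ms[2])])
    t_ms <- segment_times_ms(fx)
    idx <- which(t_ms > 1e-9 & t_ms <= w + 1e-9)
    i <- idx[which.max(xs[idx]^2 + ys[idx]^2)]
    pfx <- list(value = xs[i], time_ms = t_ms[i],
                sign_matches = xs[i] >= 0)
    pfy <- list(value = ys[i], time_ms = t_ms[i],
                sign_matches = ys[i] <= 0)
  } else {
    pfx <- peak_axis(fx, w, +1, config$baseline_ms)
    pfy <- peak_axis(fy, w, -1, config$baseline_ms)
  }
  peak_abs <- function(name) {
    ch <- epoch$channels[[name]]
    if (is.null(ch)) return(NA_real_)
    p1 <- peak_axis(ch, w, +1, config$baseline_ms)
    p2 <- peak_axis(ch, w, -1, config$baseline_ms)
    if (abs(p1$value) >= abs(p2$value)) p1$value else p2$value
  }
  rv <- resultant_vector(pfx$value, pfy$value)
  data.frame(trial = epoch$trial,
             peak_fx_n = pfx$value, peak_fy_n = pfy$value,
             peak_mx_nm = peak_abs("Mx"), peak_my_nm = peak_abs("My"),
             magnitude_n = rv$magnitude, direction_deg = rv$direction_deg,
             fx_sign_ok = pfx$sign_matches, fy_sign_ok = pfy$sign_matches,
             stringsAsFactors = FALSE)
}

#' Circular mean of directions in degrees
#'
#' Vector mean of unit vectors; immune to wrap-around at the +/-180 degree
#' boundary. `NA` directions are dropped.
#'
#' @param deg Directions in degrees.
#' @return Mean direction in `(-180, 180]`, or `NA` if no finite input.
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (!length(deg)) return(NA_real_)
  th <- deg * pi / 180
  atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
}

#' Average force vectors over the trials of one condition
#'
#' Magnitudes and per-axis peaks are averaged arithmetically; the direction
#' is averaged circularly (unit-vector mean).
#'
#' @param vectors Data frame of per-trial rows from [analyze_force_trial()].
#' @param subject_id,condition Identifiers copied into the summary.
#' @return One-row data frame of condition means plus `n_trials`.
#' @export
force_condition_summary <- function(vectors, subject_id = NA, condition = NA) {
  if (is.null(vectors) || nrow(vectors) == 0L)
    stop("force_condition_summary: empty vector table")
  data.frame(subject_id = subject_id, condition = condition,
             peak_fx_n = mean(vectors$peak_fx_n),
             peak_fy_n = mean(vectors$peak_fy_n),
             peak_mx_nm = mean(vectors$peak_mx_nm),
             peak_my_nm = mean(vectors$peak_my_nm),
             magnitude_n = mean(vectors$magnitude_n),
             direction_deg = circular_mean_deg(vectors$direction_deg),
             n_trials = nrow(vectors),
             stringsAsFactors = FALSE)
}
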