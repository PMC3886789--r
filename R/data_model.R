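## Domain containers and bundle I/O.
##
## A "recording" is one subject x condition session: a set of channels (EMG
## and force channels may run at different rates), the stimulus events, and
## the experiment layout (task, condition, joint angles, subject id). On disk
## a recording is a directory bundle of delimited text plus JSON metadata so
## that everything round-trips losslessly through plain files.

#' Construct a channel time series
#'
#' @param name Channel label, e.g. `"PD"` or `"Fx"`.
#' @param samples Numeric vector of samples (EMG in volt-equivalent arbitrary
#'   units, forces in newtons, moments in newton-meters).
#' @param rate Sampling rate in Hz (> 0).
#' @param units Unit string; defaults to `"au"` for EMG-like channels.
#' @param start_s Time of the first sample in seconds from recording start.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(name, samples, rate, units = "au", start_s = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("channel '", name, "': samples must be a non-empty numeric vector")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("channel '", name, "': rate must be a single positive number")
  structure(
    list(name = name, samples = as.numeric(samples), rate = as.numeric(rate),
         units = units, start_s = as.numeric(start_s)),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %g Hz [%s]\n",
              x$name, length(x$samples), x$rate, x$units))
  invisible(x)
}

## Sample times of a channel_series, in seconds.
#' @noRd
series_times <- function(ch) {
  ch$start_s + (seq_along(ch$samples) - 1) / ch$rate
}

#' Construct a stimulus event table
#'
#' One row per stimulus train. Train defaults follow the standard
#' reflex-eliciting train: 10 pulses of 200 microseconds at 300 Hz.
#'
#' @param onset_time_s Numeric vector of train onsets, seconds from recording
#'   start (all >= 0).
#' @param n_pulses,pulse_width_us,pulse_rate_hz,intensity_ma Train parameters,
#'   recycled to the number of events.
#' @return Data frame with one row per event, sorted by onset, with an added
#'   `train_duration_s` column equal to `(n_pulses - 1) / pulse_rate_hz`.
#' @export
stimulus_events <- function(onset_time_s, n_pulses = 10, pulse_width_us = 200,
                            pulse_rate_hz = 300, intensity_ma = NA_real_) {
  if (any(onset_time_s < 0)) stop("event onset times must be >= 0")
  if (any(n_pulses < 1)) stop("n_pulses must be >= 1")
  ev <- data.frame(onset_time_s = as.numeric(onset_time_s),
                   n_pulses = as.integer(n_pulses),
                   pulse_width_us = as.numeric(pulse_width_us),
                   pulse_rate_hz = as.numeric(pulse_rate_hz),
                   intensity_ma = as.numeric(intensity_ma))
  ev <- ev[order(ev$onset_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev$train_duration_s <- (ev$n_pulses - 1) / ev$pulse_rate_hz
  ev
}

#' Construct an experiment layout descriptor
#'
#' @param task `"joint_position"` or `"conditioning"`.
#' @param condition Condition label; for the joint-position task one of
#'   `POSITION_CONDITIONS$condition`, for the conditioning task one of
#'   `CONDITIONING_CONDITIONS`.
#' @param subject_id Subject identifier.
#' @param elbow_angle,shoulder_angle Joint angles in degrees; defaulted from
#'   the condition label where known (conditioning conditions use the neutral
#'   95/95 configuration).
#' @return A list of class `experiment_layout`.
#' @export
experiment_layout <- function(task = c("joint_position", "conditioning"),
                              condition, subject_id,
                              elbow_angle = NULL, shoulder_angle = NULL) {
  task <- match.arg(task)
  if (task == "joint_position") {
    row <- POSITION_CONDITIONS[POSITION_CONDITIONS$condition == condition, ]
    if (nrow(row) == 0L)
      stop("unknown joint_position condition '", condition, "'")
    if (is.null(elbow_angle)) elbow_angle <- row$elbow_angle
    if (is.null(shoulder_angle)) shoulder_angle <- row$shoulder_angle
  } else {
    if (!condition %in% CONDITIONING_CONDITIONS)
      stop("unknown conditioning condition '", condition, "'")
    if (is.null(elbow_angle)) elbow_angle <- 95
    if (is.null(shoulder_angle)) shoulder_angle <- 95
  }
  structure(list(task = task, condition = condition,
                 subject_id = as.character(subject_id),
                 elbow_angle = as.numeric(elbow_angle),
                 shoulder_angle = as.numeric(shoulder_angle)),
            class = "experiment_layout")
}

#' Assemble a recording from channels, events and layout
#'
#' @param channels List of [channel_series()] objects (names taken from the
#'   channel labels).
#' @param events Event table from [stimulus_events()].
#' @param layout [experiment_layout()] descriptor.
#' @return An object of class `nwr_recording`.
#' @export
nwr_recording <- function(channels, events, layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  if (!length(channels)) stop("a recording needs at least one channel")
  nm <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate channel names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(channels) <- nm
  structure(list(channels = channels, events = events, layout = layout),
            class = "nwr_recording")
}

#' @export
print.nwr_recording <- function(x, ...) {
  cat(sprintf("<nwr_recording> %s / %s / subject %s: %d channels, %d events\n",
              x$layout$task, x$layout$condition, x$layout$subject_id,
              length(x$channels), nrow(x$events)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Bundle writer / reader

#' Write a recording to a directory bundle
#'
#' The bundle holds `channels.json` (per-channel name, units, rate, start time
#' and data file), one wide CSV per sampling-rate group with a `time_s` column
#' plus one column per channel, `events.csv`, and `layout.json`.
#'
#' @param recording An `nwr_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nwr_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  chs <- recording$channels
  key <- vapply(chs, function(ch) sprintf("%g-%g", ch$rate, ch$start_s),
                character(1))
  groups <- split(seq_along(chs), key)
  meta <- list()
  gi <- 0L
  for (idx in groups) {
    gi <- gi + 1L
    f <- sprintf("channels_g%d.csv", gi)
    first <- chs[[idx[1]]]
    df <- data.frame(time_s = series_times(first))
    for (i in idx) {
      if (length(chs[[i]]$samples) != nrow(df))
        stop("channels in one rate group must have equal length")
      df[[chs[[i]]$name]] <- chs[[i]]$samples
      meta[[length(meta) + 1L]] <- list(name = chs[[i]]$name,
                                        units = chs[[i]]$units,
                                        rate_hz = chs[[i]]$rate,
                                        start_s = chs[[i]]$start_s,
                                        file = f)
    }
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(path, f), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(meta, file.path(path, "channels.json"),
                       auto_unbox = TRUE, digits = NA)
  ev <- recording$events
  ev$train_duration_s <- NULL
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(recording$layout), file.path(path, "layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording bundle
#'
#' Reads the bundle format written by [write_recording()], or an external
#' folder layout described by an adapter configuration (see
#' [read_bundle_adapter()]).
#'
#' @param path Bundle directory.
#' @param schema Optional character vector of channel names that must be
#'   present; a missing channel is a format error naming that channel.
#' @param adapter Optional adapter configuration (a list, or a path to a YAML
#'   file) mapping an external folder's files/columns onto this schema.
#' @return An `nwr_recording` with events sorted by onset time. No resampling
#'   is performed; each channel keeps its own clock.
#' @export
read_recording <- function(path, schema = NULL, adapter = NULL) {
  if (!is.null(adapter)) return(read_recording_adapter(path, schema, adapter))
  if (!dir.exists(path)) stop("no such bundle directory: ", path)
  meta <- jsonlite::read_json(file.path(path, "channels.json"),
                              simplifyVector = FALSE)
  tabs <- new.env(parent = emptyenv())
  channels <- list()
  for (m in meta) {
    if (is.null(tabs[[m$file]]))
      tabs[[m$file]] <- utils::read.csv(file.path(path, m$file),
                                        check.names = FALSE)
    df <- tabs[[m$file]]
    if (is.null(df[[m$name]]))
      stop("bundle format error: channel '", m$name,
           "' listed in channels.json but absent from ", m$file)
    tt <- df$time_s
    if (any(diff(tt) <= 0))
      stop("bundle format error: non-monotonic time in ", m$file)
    channels[[m$name]] <- channel_series(m$name, df[[m$name]],
                                         rate = m$rate_hz, units = m$units,
                                         start_s = m$start_s)
  }
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(channels))
    if (length(missing))
      stop("bundle format error: missing required channel(s): ",
           paste(missing, collapse = ", "))
  }
  ev <- utils::read.csv(file.path(path, "events.csv"))
  ev <- stimulus_events(ev$onset_time_s, ev$n_pulses, ev$pulse_width_us,
                        ev$pulse_rate_hz, ev$intensity_ma)
  lay <- jsonlite::read_json(file.path(path, "layout.json"),
                             simplifyVector = TRUE)
  layout <- experiment_layout(lay$task, lay$condition, lay$subject_id,
                              lay$elbow_angle, lay$shoulder_angle)
  nwr_recording(channels, ev, layout)
}

#' Read the bundled adapter template for external folder layouts
#'
#' Deposited data folders from other acquisition pipelines do not document a
#' fixed internal layout, so the mapping from their files and column names to
#' this package's schema is kept in an editable YAML configuration. The
#' installed template (`extdata/deposited_adapter.yaml`) documents every key;
#' copy and edit it to match the actual files before use.
#'
#' @param path Path to an adapter YAML; defaults to the installed template.
#' @return Adapter configuration list for [read_recording()].
#' @export
read_bundle_adapter <- function(path = system.file("extdata",
                                                   "deposited_adapter.yaml",
                                                   package = "nwreflex")) {
  yaml::read_yaml(path)
}

#' @noRd
read_recording_adapter <- function(path, schema, adapter) {
  if (is.character(adapter)) adapter <- yaml::read_yaml(adapter)
  channels <- list()
  for (grp in adapter$channels) {
    df <- utils::read.csv(file.path(path, grp$file), check.names = FALSE)
    tcol <- if (!is.null(grp$time_column)) grp$time_column else "time_s"
    start_s <- if (!is.null(df[[tcol]])) df[[tcol]][1] else 0
    for (orig in names(grp$map)) {
      canon <- grp$map[[orig]]
      if (is.null(df[[orig]]))
        stop("adapter error: column '", orig, "' not found in ", grp$file)
      units <- if (canon %in% FORCE_CHANNELS)
        (if (startsWith(canon, "M")) "N.m" else "N") else "au"
      channels[[canon]] <- channel_series(canon, df[[orig]],
                                          rate = grp$rate_hz, units = units,
                                          start_s = start_s)
    }
  }
  evc <- adapter$events
  ev <- utils::read.csv(file.path(path, evc$file), check.names = FALSE)
  onset <- ev[[evc$onset_column]]
  ev <- stimulus_events(
    onset,
    n_pulses = if (!is.null(evc$n_pulses)) evc$n_pulses else 10,
    pulse_width_us = if (!is.null(evc$pulse_width_us)) evc$pulse_width_us else 200,
    pulse_rate_hz = if (!is.null(evc$pulse_rate_hz)) evc$pulse_rate_hz else 300)
  lay <- adapter$layout
  layout <- experiment_layout(lay$task, lay$condition, lay$subject_id,
                              lay$elbow_angle, lay$shoulder_angle)
  rec <- nwr_recording(channels, ev, layout)
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(rec$channels))
    if (length(missing))
      stop("bundle format error: missing required channel(s): ",
           paste(missing, collapse = ", "))
  }
  rec
}

## ---------------------------------------------------------------------------
## Epoching

#' Construct a stimulus-locked channel segment
#'
#' A segment is one channel's samples around one stimulus, with `i0` the index
#' of the sample at time zero (the first sample at or after the stimulus).
#' Relative time of sample `j` is `(j - i0) / rate * 1000` ms. All window
#' arguments in this package are closed-open `[start, end)` in ms.
#'
#' @param samples Numeric samples.
#' @param rate Sampling rate in Hz.
#' @param i0 Index (1-based) of the time-zero sample.
#' @param name Channel label.
#' @return Object of class `channel_segment`.
#' @export
channel_segment <- function(samples, rate, i0, name = "") {
  stopifnot(is.numeric(samples), length(samples) >= 1, rate > 0,
            i0 >= 1, i0 <= length(samples))
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 i0 = as.integer(i0), name = name),
            class = "channel_segment")
}

#' Relative sample times of a segment in ms
#' @param seg A `channel_segment`.
#' @return Numeric vector, ms relative to stimulus onset.
#' @export
segment_times_ms <- function(seg) {
  (seq_along(seg$samples) - seg$i0) / seg$rate * 1000
}

## Indices of samples with relative time in [start_ms, end_ms).
#' @noRd
window_idx <- function(seg, start_ms, end_ms) {
  t_ms <- segment_times_ms(seg)
  which(t_ms >= start_ms - 1e-9 & t_ms < end_ms - 1e-9)
}

#' Cut stimulus-locked epochs out of a recording
#'
#' One epoch per stimulus event; every channel is cut on its own clock against
#' the shared event time (no resampling). The time-zero sample of each channel
#' is the first sample at or after the event time. Events too close to the
#' recording edges are skipped with a warning, not an error.
#'
#' @param recording An `nwr_recording`.
#' @param pre_ms Pre-stimulus span to include (>= 100 recommended; baseline
#'   statistics use the 100 ms immediately before the stimulus).
#' @param post_ms Post-stimulus span (>= 350 covers both the 200 ms reflex
#'   window and the 350 ms practice-trial force window).
#' @return List of `trial_epoch` objects, each holding per-channel
#'   [channel_segment()]s, the event time `t0_s`, and the window spans.
#' @export
segment_trials <- function(recording, pre_ms = 100, post_ms = 350) {
  stopifnot(inherits(recording, "nwr_recording"), pre_ms > 0, post_ms > 0)
  epochs <- list()
  for (e in seq_len(nrow(recording$events))) {
    t_ev <- recording$events$onset_time_s[e]
    segs <- list()
    ok <- TRUE
    for (ch in recording$channels) {
      # first sample index at or after the event on this channel's clock
      i0 <- as.integer(ceiling((t_ev - ch$start_s) * ch$rate - 1e-9)) + 1L
      n_pre <- as.integer(ceiling(pre_ms * ch$rate / 1000 - 1e-9))
      n_post <- as.integer(ceiling(post_ms * ch$rate / 1000 - 1e-9))
      lo <- i0 - n_pre
      hi <- i0 + n_post - 1L
      if (lo < 1L || hi > length(ch$samples) || i0 < 1L) {
        ok <- FALSE
        break
      }
      segs[[ch$name]] <- channel_segment(ch$samples[lo:hi], ch$rate,
                                         i0 = n_pre + 1L, name = ch$name)
    }
    if (!ok) {
      warning(sprintf("event %d at %.3f s skipped: too close to recording edge [EDGE_SKIP]",
                      e, t_ev), call. = FALSE)
      next
    }
    epochs[[length(epochs) + 1L]] <-
      structure(list(channels = segs, t0_s = t_ev,
                     pre_ms = pre_ms, post_ms = post_ms,
                     trial = length(epochs) + 1L),
                class = "trial_epoch")
  }
  epochs
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf("<trial_epoch> t0 = %.3f s, [-%g, +%g) ms, %d channels\n",
              x$t0_s, x$pre_ms, x$post_ms, length(x$channels)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Results writer

#' Write result tables to delimited text
#'
#' Writes `emg_summary.csv` (one row per subject x condition x muscle),
#' `force_summary.csv` (one row per subject x condition) and `stats.csv`
#' (one row per measure x contrast). Re-reading reproduces integer columns
#' bit-exactly and reals to full printed precision (15 significant digits).
#'
#' @param tables Named list with any of `emg_summary`, `force_summary`,
#'   `stats` data frames; empty data frames produce header-only files.
#' @param path Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("emg_summary", "force_summary", "stats")) {
    if (is.null(tables[[nm]])) next
    f <- file.path(path, paste0(nm, ".csv"))
    df <- tables[[nm]]
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                  trim = TRUE,
                                                  scientific = FALSE))
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}
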