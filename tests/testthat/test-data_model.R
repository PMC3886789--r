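# Recording containers, bundle round-trips, epoching, results writer.

test_that("recording bundles round-trip losslessly through the directory format", {
  spec <- test_spec(seed = 11)
  set.seed(11)
  # minimal bundle: one EMG channel plus Fx/Fy at a different rate, one event
  ch <- list(channel_series("PD", rnorm(600), 500),
             channel_series("Fx", rnorm(240), 200, units = "N"),
             channel_series("Fy", rnorm(240), 200, units = "N"))
  rec <- nwr_recording(ch, stimulus_events(0.6, intensity_ma = 35),
                       experiment_layout("joint_position", "NEUT", "S01"))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  back <- read_recording(d)
  expect_length(back$channels, 3)
  expect_equal(nrow(back$events), 1)
  expect_equal(back$channels$PD$samples, rec$channels$PD$samples,
               tolerance = 1e-12)
  expect_equal(back$channels$Fx$rate, 200)
  expect_equal(back$events$onset_time_s, 0.6)
  expect_equal(back$layout$condition, "NEUT")
  expect_equal(back$layout$elbow_angle, 95)

  # a full generator bundle: 8 EMG + 6 force channels, n_trials events
  ex <- gen_experiment(spec, "joint_position")
  rec2 <- ex$recordings[[1]]
  d2 <- withr::local_tempdir()
  write_recording(rec2, d2)
  back2 <- read_recording(d2, schema = c(EMG_CHANNELS, FORCE_CHANNELS))
  expect_length(back2$channels, 14)
  expect_equal(nrow(back2$events), spec$n_trials)
  for (nm in names(rec2$channels))
    expect_equal(back2$channels[[nm]]$samples, rec2$channels[[nm]]$samples,
                 tolerance = 1e-12)
})

test_that("a bundle missing a required channel errors naming that channel", {
  set.seed(2)
  ch <- list(channel_series("PD", rnorm(300), 500),
             channel_series("Fx", rnorm(120), 200, units = "N"))
  rec <- nwr_recording(ch, stimulus_events(0.3),
                       experiment_layout("joint_position", "NEUT", "S01"))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  expect_error(read_recording(d, schema = c("Fx", "Fy")), "Fy")
})

test_that("non-monotonic time in a channel file is a format error", {
  set.seed(3)
  ch <- list(channel_series("PD", rnorm(100), 500))
  rec <- nwr_recording(ch, stimulus_events(0.1),
                       experiment_layout("joint_position", "NEUT", "S01"))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  f <- file.path(d, "channels_g1.csv")
  df <- read.csv(f)
  df$time_s[5] <- df$time_s[2]
  write.csv(df, f, row.names = FALSE)
  expect_error(read_recording(d), "non-monotonic")
})

test_that("segment_trials yields one epoch per interior event with aligned clocks", {
  spec <- test_spec(seed = 21, n_trials = 8, n_subjects = 1)
  ex <- gen_experiment(spec, "joint_position")
  rec <- ex$recordings[[1]]
  eps <- segment_trials(rec, pre_ms = 100, post_ms = 350)
  expect_length(eps, 8)
  # epoch t0 matches the generator's event times within one sample period
  for (i in seq_along(eps)) {
    expect_equal(eps[[i]]$t0_s, rec$events$onset_time_s[i])
    for (ch in eps[[i]]$channels) {
      t_ms <- segment_times_ms(ch)
      expect_lt(t_ms[ch$i0], 1000 / ch$rate)   # time-zero sample at/after event
      expect_gte(t_ms[ch$i0], 0)
      expect_lte(min(t_ms), -100 + 1e-9)
      expect_gte(max(t_ms), 350 - 1000 / ch$rate - 1e-9)
    }
  }
  # epoch sample times are original recording times shifted by the event
  pd <- rec$channels$PD
  seg <- eps[[3]]$channels$PD
  orig <- pd$start_s + (seq_along(pd$samples) - 1) / pd$rate
  i0_glob <- which(orig >= eps[[3]]$t0_s)[1]
  expect_equal(segment_times_ms(seg) / 1000 + orig[i0_glob],
               orig[(i0_glob - seg$i0 + 1):(i0_glob - seg$i0 + length(seg$samples))],
               tolerance = 1e-9)
})

test_that("events too close to the recording edge are skipped with a warning", {
  set.seed(5)
  ch <- list(channel_series("PD", rnorm(500), 500))
  rec <- nwr_recording(ch, stimulus_events(0.05),  # < 100 ms of pre-samples
                       experiment_layout("joint_position", "NEUT", "S01"))
  expect_warning(eps <- segment_trials(rec, 100, 350), "skipped")
  expect_length(eps, 0)
})

test_that("epoch count is invariant under channel order permutation", {
  spec <- test_spec(seed = 22, n_subjects = 1, n_trials = 3)
  rec <- gen_experiment(spec, "joint_position")$recordings[[1]]
  eps1 <- segment_trials(rec, 100, 350)
  rec$channels <- rev(rec$channels)
  eps2 <- segment_trials(rec, 100, 350)
  expect_length(eps2, length(eps1))
  expect_equal(eps1[[1]]$channels$PD$samples, eps2[[1]]$channels$PD$samples)
})

test_that("write_results produces the documented row layout and round-trips", {
  d <- withr::local_tempdir()
  # header-only files from empty tables
  empty <- data.frame(subject_id = character(), condition = character(),
                      muscle = character(), onset_mean_ms = numeric())
  write_results(list(emg_summary = empty), d)
  expect_equal(nrow(read.csv(file.path(d, "emg_summary.csv"))), 0)

  # 10 subjects x 6 conditions x 8 muscles -> 480-row EMG table
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:10),
                      condition = POSITION_CONDITIONS$condition,
                      muscle = EMG_CHANNELS, stringsAsFactors = FALSE)
  grid$onset_mean_ms <- runif(nrow(grid), 50, 100)
  grid$n_trials_used <- 8L
  write_results(list(emg_summary = grid), d)
  back <- read.csv(file.path(d, "emg_summary.csv"))
  expect_equal(nrow(back), 480)
  expect_equal(back$onset_mean_ms, grid$onset_mean_ms, tolerance = 1e-12)
  expect_identical(back$n_trials_used, grid$n_trials_used)
})

test_that("adapter configuration maps an external folder onto the schema", {
  d <- withr::local_tempdir()
  set.seed(9)
  t_emg <- seq(0, 2, by = 1 / 500)
  emg <- data.frame(time_s = t_emg)
  for (m in tolower(EMG_CHANNELS)) emg[[m]] <- rnorm(length(t_emg))
  write.csv(emg, file.path(d, "emg.csv"), row.names = FALSE)
  t_f <- seq(0, 2, by = 1 / 200)
  frc <- data.frame(time_s = t_f)
  for (m in tolower(FORCE_CHANNELS)) frc[[m]] <- rnorm(length(t_f))
  write.csv(frc, file.path(d, "force.csv"), row.names = FALSE)
  write.csv(data.frame(onset_s = 1.0), file.path(d, "stim.csv"),
            row.names = FALSE)

  adapter <- read_bundle_adapter()
  adapter$channels[[1]]$rate_hz <- 500
  rec <- read_recording(d, schema = c(EMG_CHANNELS, FORCE_CHANNELS),
                        adapter = adapter)
  expect_length(rec$channels, 14)
  expect_equal(rec$channels$PD$samples, emg$pd)
  expect_equal(rec$channels$Fy$rate, 200)
  expect_equal(rec$events$n_pulses, 10L)
  expect_equal(rec$layout$condition, "EXT_PRE")
})
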