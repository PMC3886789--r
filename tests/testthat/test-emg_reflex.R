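# EMG chain: DC removal, rectification, baseline, onset detection (vs an
# exhaustive scan oracle), response quantification, condition averaging.

test_that("remove_dc zeroes the epoch mean and is idempotent on zero-mean input", {
  t <- seq(0, 0.5, by = 1 / 1000)
  seg <- channel_segment(sin(2 * pi * 40 * t) + 2.1, 1000, 101)
  out <- remove_dc(seg)
  expect_lt(abs(mean(out$samples)), 1e-12 * 2.1)
  expect_equal(length(out$samples), length(seg$samples))
  # sine + offset 2.1 -> sine (up to the tiny mean of the finite sine window)
  expect_equal(out$samples, sin(2 * pi * 40 * t) - mean(sin(2 * pi * 40 * t)),
               tolerance = 1e-12)
  expect_equal(remove_dc(out)$samples, out$samples)
  # constant input collapses to zeros
  expect_equal(remove_dc(channel_segment(rep(5, 10), 100, 5))$samples,
               rep(0, 10))
})

test_that("rectify is |x|, idempotent, and identity on non-negative input", {
  seg <- channel_segment(c(-1, 2, -3), 100, 1)
  expect_equal(rectify(seg)$samples, c(1, 2, 3))
  expect_equal(rectify(rectify(seg))$samples, rectify(seg)$samples)
  nn <- channel_segment(c(0, 1, 2), 100, 1)
  expect_equal(rectify(nn)$samples, nn$samples)
})

test_that("downstream operations reject un-rectified input by contract", {
  seg <- channel_segment(rnorm(200), 500, 101)
  expect_error(baseline_stats(seg), "rectified")
  b <- baseline_stats(rectify(seg))
  expect_error(detect_onset(seg, b), "rectified")
  expect_error(quantify_response(seg, 10, 50), "rectified")
})

test_that("baseline statistics match hand computation and sample counts", {
  # samples [1,2,3,4] in the window: mean 2.5, sd (n-1) = 1.290994
  seg <- make_rect_segment(c(1, 2, 3, 4, 9, 9), rate = 40, i0 = 5)
  b <- baseline_stats(seg, c(-100, 0))
  expect_equal(b$mean, 2.5)
  expect_equal(b$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(b$n, 4)
  # constant window: mean c, sd 0
  segc <- make_rect_segment(rep(c(7, 0), c(20, 70)), rate = 200, i0 = 21)
  bc <- baseline_stats(segc, c(-100, 0))
  expect_equal(bc$mean, 7); expect_equal(bc$sd, 0)
  # at 200 Hz a 100 ms window holds 20 samples
  expect_equal(bc$n, 20)
  # window outside the epoch errors
  expect_error(baseline_stats(segc, c(-500, 0)), "not covered")
})

test_that("onset detection follows the sustained 3-SD crossing rule", {
  rate <- 1000
  n <- 450; i0 <- 101
  base <- rep(0.1, n)  # constant baseline: threshold = mean + 3*0 = 0.1
  # signal never above threshold -> absent
  seg0 <- make_rect_segment(base, rate, i0)
  expect_true(is.na(detect_onset(seg0, baseline_stats(seg0))$onset_ms))
  # sustained boxcar at 80 ms -> onset 80 within one sample
  x <- base; x[(i0 + 80):(i0 + 120)] <- 1
  seg <- make_rect_segment(x, rate, i0)
  det <- detect_onset(seg, baseline_stats(seg), min_above_ms = 0)
  expect_lt(abs(det$onset_ms - 80), 1000 / rate + 1e-9)
  # isolated single-sample spike at 30 ms is ignored with 2 ms debounce,
  # but is returned by the literal first-crossing rule (min_above_ms = 0)
  x2 <- x; x2[i0 + 30] <- 2
  seg2 <- make_rect_segment(x2, rate, i0)
  expect_equal(detect_onset(seg2, baseline_stats(seg2), min_above_ms = 2)$onset_ms,
               det$onset_ms)
  expect_equal(detect_onset(seg2, baseline_stats(seg2), min_above_ms = 0)$onset_ms,
               30)
  # degenerate all-zero baseline: warn, proceed with threshold 0
  xz <- rep(0, n); xz[(i0 + 50):(i0 + 90)] <- 1
  segz <- make_rect_segment(xz, rate, i0)
  expect_warning(dz <- detect_onset(segz, baseline_stats(segz)), "degenerate")
  expect_equal(dz$onset_ms, 50)
})

test_that("detector equals the exhaustive scan oracle on random epochs", {
  set.seed(77)
  n_cases <- 200
  for (i in seq_len(n_cases)) {
    rate <- sample(c(500, 1000, 2000), 1)
    spec <- synthetic_spec(seed = 1, emg_rate = rate,
                           true_latency_ms = c(PD = runif(1, 50, 100)),
                           burst_amplitude = runif(1, 3.5, 8),
                           latency_jitter_sd_ms = runif(1, 0, 6))
    tr <- suppressWarnings(gen_emg_trial(spec, "PD"))
    r <- rectify(remove_dc(tr$segment))
    b <- baseline_stats(r)
    mab <- sample(c(0, 1, 2, 5), 1)
    det <- detect_onset(r, b, min_above_ms = mab)
    oracle <- scan_onset_oracle(r, det$threshold, min_above_ms = mab)
    expect_identical(det$onset_ms, oracle)
  }
})

test_that("raising the threshold multiplier never yields an earlier onset", {
  set.seed(78)
  spec <- synthetic_spec(seed = 1, emg_rate = 1000)
  for (i in 1:50) {
    tr <- gen_emg_trial(spec, sample(c("PD", "BRD", "TRI"), 1))
    r <- rectify(remove_dc(tr$segment))
    b <- baseline_stats(r)
    o3 <- detect_onset(r, b, k = 3)$onset_ms
    o4 <- detect_onset(r, b, k = 4)$onset_ms
    if (!is.na(o4)) {
      expect_false(is.na(o3))
      expect_gte(o4, o3)
    }
  }
})

test_that("response quantification is the windowed mean of rectified samples", {
  seg <- make_rect_segment(rep(2, 300), 1000, 101)
  expect_equal(quantify_response(seg, 20, 120), 2)
  # boxcar of amplitude A over exactly the window -> A
  x <- rep(0.0, 300); x[(101 + 50):(101 + 99)] <- 3.5
  segb <- make_rect_segment(x, 1000, 101)
  expect_equal(quantify_response(segb, 50, 100), 3.5)
  # equality with a direct summation oracle on arbitrary samples
  set.seed(12)
  xr <- abs(rnorm(300))
  segr <- make_rect_segment(xr, 1000, 101)
  t_ms <- segment_times_ms(segr)
  idx <- which(t_ms >= 30 & t_ms < 170)
  expect_equal(quantify_response(segr, 30, 170), sum(xr[idx]) / length(idx))
  # absent onset propagates
  expect_true(is.na(quantify_response(segr, NA, 170)))
})

test_that("condition summaries average detected trials and count the rest", {
  resp <- data.frame(trial = 1:8, muscle = "PD",
                     onset_ms = rep(77.5, 8), offset_ms = 200,
                     mean_emg = rep(0.02, 8), threshold = 0.01)
  s <- summarize_condition(resp, "S01", "NEUT")
  expect_equal(s$onset_mean_ms, 77.5)
  expect_equal(s$onset_sd_ms, 0)
  expect_equal(s$n_trials_used, 8)
  # 7 detections of 8
  resp$onset_ms[3] <- NA; resp$mean_emg[3] <- NA
  s7 <- summarize_condition(resp, "S01", "NEUT")
  expect_equal(s7$n_trials_used, 7)
  expect_equal(s7$n_trials, 8)
  # a muscle with zero detections is flagged absent, not dropped
  es <- data.frame(trial = 1:8, muscle = "ESR", onset_ms = NA_real_,
                   offset_ms = 200, mean_emg = NA_real_, threshold = 0.01)
  se <- summarize_condition(rbind(resp, es), "S01", "NEUT")
  expect_true(is.na(se$onset_mean_ms[se$muscle == "ESR"]))
  expect_equal(se$n_trials_used[se$muscle == "ESR"], 0)
  expect_error(summarize_condition(resp[0, ]), "empty")
})

test_that("grand-mean latency is recovered from a synthetic condition", {
  # true latency 78, jitter 5 ms, 8 trials x 10 subject-level replicates:
  # the grand mean of detected onsets should sit within 2 SEM of truth plus
  # the small positive crossing bias (< 1 ms)
  spec <- synthetic_spec(seed = 1, emg_rate = 2000)
  set.seed(90)
  onsets <- replicate(80, {
    tr <- gen_emg_trial(spec, "PD")
    detect_on_trial(tr) - tr$true_onset_ms
  })
  expect_gt(mean(!is.na(onsets)), 0.95)
  err <- onsets[!is.na(onsets)]
  expect_lt(abs(mean(err)), 1 + 2 * sd(err) / sqrt(length(err)))
})

test_that("default bursts are detected within 2 ms on at least 95% of trials", {
  # detectability-by-design at the default spec (burst 5x baseline SD),
  # asserted with a one-sided 3-SE Monte-Carlo allowance on the 95% bound
  spec <- synthetic_spec(seed = 1)
  set.seed(101)
  n <- 600
  hit <- logical(n)
  for (i in seq_len(n)) {
    tr <- gen_emg_trial(spec, "PD")
    on <- detect_on_trial(tr)
    hit[i] <- !is.na(on) && abs(on - tr$true_onset_ms) <= 2
  }
  expect_gte(mean(hit), 0.95 - 3 * sqrt(0.95 * 0.05 / n))
})

test_that("baseline-only trials rarely trigger the debounced detector", {
  # false-positive control: noise-only channels, 2 ms debounce
  spec <- synthetic_spec(seed = 1)
  set.seed(102)
  n <- 400
  fp <- logical(n)
  for (i in seq_len(n)) {
    tr <- gen_emg_trial(spec, "ESR")
    fp[i] <- !is.na(detect_on_trial(tr))
  }
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})
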