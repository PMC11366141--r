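test_that("resampling is the identity on a 10 Hz input and preserves constants", {
  t10 <- seq(0, 60, by = 0.1)
  rec <- accel_recording(t10, cbind(0.3, 0.3, 0.3 + 0 * t10), 10)
  expect_identical(resample_to_10hz(rec), rec)

  t125 <- seq(0, 60, by = 0.08)
  rec2 <- accel_recording(t125, cbind(0.7, 0.7, 0.7 + 0 * t125), 12.5)
  out <- resample_to_10hz(rec2)
  expect_equal(out$sample_rate_hz, 10)
  expect_equal(unique(round(diff(out$time_s), 9)), 0.1)
  expect_equal(max(abs(out$acc - 0.7)), 0)
})

test_that("resampling a sinusoid matches the closed form within the interpolation bound", {
  t <- seq(0, 60, by = 0.08)
  rec <- accel_recording(t, cbind(sin(2 * pi * t), 0, 0), 12.5)
  out <- resample_to_10hz(rec)
  # linear interpolation error bound: A (2 pi f)^2 h^2 / 8 = 0.0316 g
  expect_lt(max(abs(out$acc[, 1] - sin(2 * pi * out$time_s))), 0.032)
})

test_that("resampling twice equals resampling once", {
  t <- seq(0, 120, by = 0.08)
  set.seed(1)
  rec <- accel_recording(t, matrix(rnorm(3 * length(t), 0, 0.1), ncol = 3), 12.5)
  once <- resample_to_10hz(rec)
  expect_identical(resample_to_10hz(once), once)
})

test_that("a non-uniform grid is rejected naming the first irregular gap", {
  t <- seq(0, 10, by = 0.08)
  t[50] <- t[50] + 0.01
  rec <- accel_recording(t, matrix(0, length(t), 3), 12.5)
  expect_error(resample_to_10hz(rec), "irregular gap")
})

test_that("the high-pass filter removes DC and passes 2 Hz", {
  t <- seq(0, 600, by = 0.1)
  rec <- accel_recording(t, cbind(0, 0, rep(1, length(t))), 10)
  hf <- highpass_filter(rec)
  core <- abs(hf$acc[hf$time_s > 30 & hf$time_s < 570, ])
  expect_lt(max(core), 1e-6)

  rec2 <- accel_recording(t, cbind(sin(2 * pi * 2 * t), 0, 0), 10)
  hf2 <- highpass_filter(rec2)
  keep <- hf2$time_s > 30 & hf2$time_s < 570
  amp <- sqrt(2) * stats::sd(hf2$acc[keep, 1])
  expect_lt(abs(amp - 1), 0.01) # passband amplitude within 1%

  rec3 <- accel_recording(t, cbind(sin(2 * pi * 0.02 * t), 0, 0), 10)
  hf3 <- highpass_filter(rec3)
  expect_lt(max(abs(hf3$acc[keep, 1])), 0.01) # stopband, two passes
})

test_that("too-short recordings are rejected by the filter", {
  t <- seq(0, 30, by = 0.1)
  rec <- accel_recording(t, matrix(0, length(t), 3), 10)
  expect_error(highpass_filter(rec), "too short")
})

test_that("exclusion masking merges overlapping episodes", {
  t <- seq(0, 120, by = 0.1)
  rec <- accel_recording(t, matrix(0, length(t), 3), 10)
  expect_equal(sum(mask_exclusions(rec, NULL)$excluded), 0)
  ep <- data.frame(start_s = c(0, 30), end_s = c(60, 90), reason = "x")
  m <- mask_exclusions(rec, ep)
  expect_identical(m$excluded, t >= 0 & t < 90)
})

test_that("a fully excluded recording cannot be summarized", {
  t <- seq(0, 120, by = 0.1)
  rec <- accel_recording(t, matrix(0.2, length(t), 3), 10)
  rec <- mask_exclusions(rec, data.frame(start_s = 0, end_s = 121))
  ws <- compute_sma(rec)
  expect_true(all(ws$excluded))
  expect_error(extract_features(ws), "non-excluded")
})

test_that("adding an exclusion episode never increases bouts or active time", {
  cfg <- sim_config(
    n_patients = 1, recording_hours = 0.5, bout_rate_per_hour = 8,
    bout_intensity_logmean = log(0.4), noise_sd_g = 0.01,
    exclusion_episodes_per_day = 0
  )
  for (s in 1:5) {
    set.seed(s)
    sim <- simulate_recording(cfg)
    f0 <- movement_features(sim$recording, NULL)
    ep <- data.frame(start_s = 300 * s %% 900, end_s = 300 * s %% 900 + 240)
    f1 <- movement_features(sim$recording, ep)
    expect_lte(f1$n_bouts, f0$n_bouts)
    expect_lte(
      f1$pct_active * f1$analyzed_hours,
      f0$pct_active * f0$analyzed_hours
    )
  }
})
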