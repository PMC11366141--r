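test_that("identical seed and config give bitwise-identical recordings", {
  cfg <- sim_config(n_patients = 2, recording_hours = 0.1)
  set.seed(99)
  a <- simulate_recording(cfg)
  set.seed(99)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$acc, b$recording$acc)
  expect_identical(a$exclusions, b$exclusions)
  expect_identical(a$truth, b$truth)
})

test_that("zero bout rate gives a recording with no activity downstream", {
  cfg <- sim_config(
    n_patients = 1, recording_hours = 0.2, bout_rate_per_hour = 0,
    noise_sd_g = 0.005, exclusion_episodes_per_day = 0
  )
  set.seed(1)
  sim <- simulate_recording(cfg)
  expect_equal(sim$truth$n_bouts, 0)
  f <- movement_features(sim$recording, sim$exclusions)
  expect_equal(f$pct_active, 0)
  expect_equal(f$n_bouts, 0)
  expect_true(is.na(f$ab_intensity_logmean))
})

test_that("noise-free static sensor reads gravity on the z axis only", {
  cfg <- sim_config(
    n_patients = 1, recording_hours = 0.05, bout_rate_per_hour = 0,
    noise_sd_g = 0, exclusion_episodes_per_day = 0,
    gravity_orientation = c(0, 0, 1)
  )
  set.seed(1)
  sim <- simulate_recording(cfg)
  expect_equal(max(abs(sim$recording$acc[, 1:2])), 0)
  expect_equal(unique(sim$recording$acc[, 3]), 1)
})

test_that("planted bouts are recovered at the planted count and %active", {
  # ~12 bouts of 0.5 g / 20 s in one hour: each planted bout must come
  # back out of the detector, and %active (approx 12*20/3600 = 6.7% at
  # the nominal rate) must match the planted truth to within one 5 s
  # window per bout edge
  cfg <- sim_config(
    n_patients = 1, recording_hours = 1, bout_rate_per_hour = 12,
    bout_duration_logmean = log(20), bout_duration_logsd = 1e-9,
    bout_intensity_logmean = log(0.5), bout_intensity_logsd = 1e-9,
    noise_sd_g = 0.01, exclusion_episodes_per_day = 0
  )
  set.seed(42)
  sim <- simulate_recording(cfg)
  expect_gt(sim$truth$n_bouts, 0)
  expect_equal(
    sim$truth$pct_active,
    100 * sim$truth$n_bouts * 20 / 3600,
    tolerance = 1e-6
  )
  f <- movement_features(sim$recording, sim$exclusions)
  expect_equal(f$n_bouts, sim$truth$n_bouts)
  tol_pct <- 100 * sim$truth$n_bouts * 2 * 5 / 3600
  expect_lt(abs(f$pct_active - sim$truth$pct_active), tol_pct)
  # planted intensity survives the pipeline up to window-edge dilution
  # (bouts are not window-aligned) and the 12.5 -> 10 Hz interpolation loss
  expect_lt(abs(exp(f$ab_intensity_logmean) - 0.5) / 0.5, 0.25)
})

test_that("planted-truth recovery holds across 100 seeded recordings", {
  cfg <- sim_config(
    n_patients = 1, recording_hours = 0.5, bout_rate_per_hour = 6,
    bout_intensity_logmean = log(0.4), bout_intensity_logsd = 0.2,
    detectable_bouts = TRUE, noise_sd_g = 0.01,
    exclusion_episodes_per_day = 0
  )
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    sim <- simulate_recording(cfg)
    f <- movement_features(sim$recording, sim$exclusions)
    if (f$n_bouts == sim$truth$n_bouts) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("exclusion episodes are disjoint and an empty rate gives none", {
  cfg0 <- sim_config(n_patients = 1, exclusion_episodes_per_day = 0)
  set.seed(5)
  expect_equal(nrow(simulate_exclusions(cfg0, 86400)), 0)
  cfg <- sim_config(n_patients = 1, exclusion_episodes_per_day = 20)
  set.seed(5)
  ep <- simulate_exclusions(cfg, 86400)
  expect_gt(nrow(ep), 0)
  expect_true(all(ep$start_s < ep$end_s))
  if (nrow(ep) > 1) {
    expect_true(all(ep$start_s[-1] >= ep$end_s[-nrow(ep)]))
  }
})

test_that("an exclusion episode covering a planted bout removes it downstream", {
  cfg <- sim_config(
    n_patients = 1, recording_hours = 1, bout_rate_per_hour = 4,
    bout_intensity_logmean = log(0.5), bout_intensity_logsd = 1e-9,
    noise_sd_g = 0.005, exclusion_episodes_per_day = 0
  )
  set.seed(7)
  sim <- simulate_recording(cfg)
  expect_gt(sim$truth$n_bouts, 0)
  f0 <- movement_features(sim$recording, NULL)
  b1 <- sim$truth$bouts[1, ]
  cover <- data.frame(
    start_s = b1$start_s - 5, end_s = b1$start_s + b1$duration_s + 5,
    reason = "physiotherapy"
  )
  f1 <- movement_features(sim$recording, cover)
  expect_equal(f1$n_bouts, f0$n_bouts - 1)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(residual_sd = -1), "positive")
  expect_error(sim_config(sample_rate_hz = 0.3), "Nyquist|0.4")
  expect_error(sim_config(gravity_orientation = c(1, 1, 0)), "unit")
  expect_error(sim_config(recording_hours = 0), "positive")
  expect_error(sim_config(bout_rate_per_hour = -2), "non-negative")
})
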