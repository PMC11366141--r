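test_that("SMA of simple windows matches hand arithmetic", {
  t <- seq(0, 10 - 0.1, by = 0.1)
  zero <- accel_recording(t, matrix(0, length(t), 3), 10)
  expect_equal(compute_sma(zero)$sma_g, c(0, 0))

  const <- accel_recording(t, cbind(0.1, 0.05, 0.05 + 0 * t), 10)
  expect_equal(compute_sma(const)$sma_g, c(0.2, 0.2))
})

test_that("SMA of a rectified sinusoid equals the sampled rectified mean", {
  t <- seq(0, 5 - 0.1, by = 0.1)
  for (A in c(0.2, 0.4, 0.5)) {
    rec <- accel_recording(t, cbind(A * sin(2 * pi * 2 * t), 0, 0 * t), 10)
    sma <- compute_sma(rec)$sma_g
    expect_equal(sma, mean(abs(A * sin(2 * pi * 2 * t)))) # numeric oracle
    # and it tracks the continuous closed form 2A/pi at the sampling bound
    expect_lt(abs(sma - 2 * A / pi), A * 0.034)
  }
})

test_that("windows are 5 s, trailing partials drop, excluded samples spread", {
  t <- seq(0, 12.3, by = 0.1) # 124 samples: two full windows + partial
  rec <- accel_recording(t, matrix(0.1, length(t), 3), 10)
  rec$excluded[3] <- TRUE
  ws <- compute_sma(rec)
  expect_equal(nrow(ws), 2)
  expect_identical(ws$excluded, c(TRUE, FALSE))
  short <- accel_recording(seq(0, 0.3, by = 0.1), matrix(0, 4, 3), 10)
  expect_error(compute_sma(short), "shorter than one window")
})

test_that("bout detection follows the defining example and threshold rule", {
  ws <- make_ws(c(0.20, 0.20, 0.05, 0.14))
  b <- detect_bouts(ws)
  expect_equal(nrow(b), 2)
  expect_equal(b$start_s, c(0, 15))
  expect_equal(b$duration_s, c(10, 5))
  expect_equal(b$intensity_g, c(0.20, 0.14))

  expect_equal(nrow(detect_bouts(make_ws(c(0.1, 0.13, 0.05)))), 0)
  # the threshold itself counts as active
  expect_equal(nrow(detect_bouts(make_ws(c(0.135)))), 1)
  # an excluded window breaks a run
  ws2 <- make_ws(c(0.2, 0.2, 0.2), excluded = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(detect_bouts(ws2)), 2)
})

test_that("bout detection equals the exhaustive-scan oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    sma <- round(stats::runif(n, 0, 0.3), 3)
    excl <- stats::runif(n) < 0.15
    got <- detect_bouts(make_ws(sma, excl))
    want <- bout_oracle(sma, excl)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, (want$start - 1) * 5)
      expect_equal(got$duration_s, want$len * 5)
      expect_equal(got$intensity_g, want$intensity)
    }
  }
})

test_that("log-normal MLE has its closed form and concentrates", {
  expect_equal(lognormal_mle(rep(exp(1), 4)), list(logmean = 1, logsd = 0))
  expect_equal(lognormal_mle(c(1, exp(2))), list(logmean = 1, logsd = 1))
  expect_error(lognormal_mle(c(1, -2)), "positive")
  expect_true(is.na(lognormal_mle(numeric(0))$logmean))

  set.seed(9)
  x <- stats::rlnorm(10000, -1, 0.5)
  est <- lognormal_mle(x)
  expect_lt(abs(est$logmean - (-1)), 3 * 0.5 / sqrt(10000))
  expect_lt(abs(est$logsd - 0.5), 3 * 0.5 / sqrt(2 * 10000))
})

test_that("feature aggregation matches the defining example and bookkeeping", {
  ws <- make_ws(c(0.20, 0.20, 0.05, 0.14))
  f <- extract_features(ws)
  expect_equal(f$pct_active, 75)
  expect_equal(f$n_bouts, 2)
  expect_equal(f$overall_intensity_g, 0.1475)
  # summed bout durations equal %active/100 x analyzed duration exactly
  b <- detect_bouts(ws)
  expect_equal(sum(b$duration_s), f$pct_active / 100 * f$analyzed_hours * 3600)

  static <- extract_features(make_ws(rep(0.01, 12)))
  expect_equal(static$pct_active, 0)
  expect_equal(static$ab_per_hour, 0)
  expect_true(is.na(static$ab_duration_logmean))
})
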