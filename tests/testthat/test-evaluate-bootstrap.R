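test_that("metrics follow their definitions on hand-computed cases", {
  perfect <- evaluate_predictions(1:4, 1:4)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)

  shifted <- evaluate_predictions(1:4, 1:4 + 3)
  expect_equal(shifted$r2, 1)
  expect_equal(shifted$mae, 3)

  # hand arithmetic: errors (1,0,1,0); r computed longhand is sqrt(0.8)
  ev <- evaluate_predictions(c(1, 2, 3, 4), c(2, 2, 4, 4))
  expect_equal(ev$mse, 0.5)
  expect_equal(ev$rmse, sqrt(0.5))
  expect_equal(ev$mae, 0.5)
  expect_equal(ev$r2, 0.8)

  const <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_false(const$r2_defined)
  expect_true(is.na(const$r2))
})

test_that("standardization constants come from the training portion only", {
  set.seed(1)
  tr <- matrix(rnorm(40, 5, 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  te <- matrix(rnorm(10, 5, 2), 5, 2, dimnames = list(NULL, c("a", "b")))
  zs <- zscore_fit(tr)
  expect_equal(unname(colMeans(zs$x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(zs$x, 2, sd)), c(1, 1), tolerance = 1e-9)
  z_te <- zscore_apply(zs, te)
  expect_equal(z_te, sweep(sweep(te, 2, zs$center), 2, zs$scale, "/"))
  expect_error(zscore_fit(cbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("BCa endpoints reduce to percentile when z0 = a = 0", {
  set.seed(2)
  th <- rnorm(2000)
  ci <- bca_interval(th, median(th), z0 = 0, a = 0)
  expect_equal(ci$lower, unname(quantile(th, 0.025)))
  expect_equal(ci$upper, unname(quantile(th, 0.975)))
})

test_that("a coefficient identical across resamples gives a flagged degenerate interval", {
  ci <- bca_interval(rep(0, 500), 0)
  expect_true(ci$degenerate)
  expect_equal(c(ci$lower, ci$upper), c(0, 0))
})

test_that("the cluster bootstrap produces sane intervals on a small cohort", {
  d <- make_lmm_data(3, n_pat = 25, beta = c(2, rep(0, 4)), sigma_b = 1)
  bb <- bootstrap_bca(d$x, d$y, d$cluster,
    lambda = 0.5,
    n_resamples = 200, seed = 4
  )
  ints <- bb$intervals
  # interior intervals bracket the point estimate
  ok <- !ints$degenerate
  expect_true(all(ints$lower[ok] <= ints$estimate[ok] + 1e-12))
  expect_true(all(ints$upper[ok] >= ints$estimate[ok] - 1e-12))
  # the strong effect is significant, most nulls are not
  v1 <- ints[ints$term == "v1", ]
  expect_gt(v1$lower, 0)
})

test_that("Welch's t-test matches the reference implementation and conventions", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4, 5)
  mine <- welch_ttest(a, b)
  ref <- t.test(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  same <- welch_ttest(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
})

test_that("healthy controls versus patients separate decisively", {
  # with n = 3 controls the Welch degrees of freedom sit near 2, so the
  # attainable two-sided p for even a huge separation is ~1e-3
  for (s in 1:5) {
    set.seed(s)
    healthy <- rnorm(3, 13.3, 0.8)
    nicu <- pmax(rnorm(53, 0.84, 1.08), 0)
    expect_lt(welch_ttest(healthy, nicu)$p, 0.01)
  }
})
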