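make_limb_data <- function(seed, means = c(
                             active = -5,
                             immobile_no_umnl = -20, immobile_umnl = -20
                           ),
                           n_per = 20, sd = 3) {
  set.seed(seed)
  grp <- rep(names(means), each = n_per)
  data.frame(
    patient_id = paste0("P", rep(seq_len(length(means) * n_per / 2), each = 2)),
    limb_group = grp,
    atrophy_pct = rnorm(length(grp), means[grp], sd)
  )
}

test_that("independence working correlation reproduces ordinary least squares", {
  d <- make_limb_data(1)
  g <- fit_gee_limbgroups(d, working_correlation = "independence")
  ols <- tapply(d$atrophy_pct, d$limb_group, mean)
  expect_equal(
    unname(g$coefficients[names(ols)]), as.numeric(ols),
    tolerance = 1e-8
  )
  expect_equal(g$alpha, 0)
})

test_that("planted group separation is detected and the null pair is not", {
  d <- make_limb_data(2)
  g <- fit_gee_limbgroups(d)
  ct <- g$contrasts
  act_vs <- ct[grepl("active", ct$contrast) &
    !grepl("immobile_no_umnl - immobile_umnl", ct$contrast), ]
  imm_pair <- ct[ct$contrast == "immobile_no_umnl - immobile_umnl", ]
  expect_true(all(act_vs$p_bonferroni < 0.05))
  expect_gt(imm_pair$p_bonferroni, 0.05)
})

test_that("Bonferroni adjustment multiplies by the number of contrasts", {
  d <- make_limb_data(3)
  g <- fit_gee_limbgroups(d)
  expect_equal(
    g$contrasts$p_bonferroni,
    pmin(g$contrasts$p * 3, 1)
  )
})

test_that("a single-patient group is rejected", {
  d <- make_limb_data(4)
  d$patient_id[d$limb_group == "active"] <- "P_only"
  expect_error(fit_gee_limbgroups(d), "single patient")
})

test_that("the exchangeable correlation picks up planted clustering", {
  set.seed(5)
  pat <- rep(sprintf("P%02d", 1:30), each = 2)
  u <- rnorm(30, 0, 4)[rep(1:30, each = 2)]
  d <- data.frame(
    patient_id = pat,
    limb_group = rep(c("active", "immobile_no_umnl", "immobile_umnl"), 20),
    atrophy_pct = -10 + u + rnorm(60, 0, 2)
  )
  g <- fit_gee_limbgroups(d)
  expect_gt(g$alpha, 0.5)
})

test_that("the temporalis control model reports the pct_active interval", {
  set.seed(6)
  n <- 60
  d <- data.frame(
    atrophy_pct = NA, age = rnorm(n, 60, 15), sex = rbinom(n, 1, 0.5),
    msofa = rnorm(n, 4.5, 2), calorie_deficit = rnorm(n, 6000, 2000),
    protein_deficit = rnorm(n, 300, 100), pct_active = rlnorm(n, -0.66, 0.99)
  )
  d$atrophy_pct <- -15 + 0.1 * d$age + rnorm(n, 0, 8)
  fit <- fit_ols_tm(d)
  expect_equal(nrow(fit$pct_active_ci), 1)
  expect_true(is.finite(fit$pct_active_ci$lower))

  # exact recovery when the outcome is a deterministic covariate multiple
  d2 <- d
  d2$atrophy_pct <- 2 * d2$age
  # the noiseless fixture triggers R's "essentially perfect fit" notice
  fit2 <- suppressWarnings(fit_ols_tm(d2))
  co <- fit2$coefficients
  expect_equal(co$estimate[co$term == "age"], 2, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit2$fit))), 1e-9)

  # more parameters than rows is a rank-deficiency error
  expect_error(fit_ols_tm(d[1:5, ]), "rank")
})

test_that("pct_active's interval covers zero at the nominal type-I rate", {
  covered <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 50
    d <- data.frame(
      age = rnorm(n, 60, 15), sex = rbinom(n, 1, 0.5),
      msofa = rnorm(n, 4.5, 2), calorie_deficit = rnorm(n, 6000, 2000),
      protein_deficit = rnorm(n, 300, 100),
      pct_active = rlnorm(n, -0.66, 0.99)
    )
    d$atrophy_pct <- -15.3 + rnorm(n, 0, 11.1) # independent of pct_active
    ci <- fit_ols_tm(d)$pct_active_ci
    if (ci$lower <= 0 && ci$upper >= 0) covered <- covered + 1
  }
  expect_gte(covered, 88)
  expect_lte(covered, 100)
})
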