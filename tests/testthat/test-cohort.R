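test_that("repeated ultrasound measurements average arithmetically", {
  expect_equal(average_repeats(c(10, 10, 10)), 10)
  expect_equal(average_repeats(c(9, 10, 11)), 10)
  expect_equal(average_repeats(c(10.3, 10.3, 10.3)), 10.3)
  expect_error(average_repeats(c(10, 11)), "three")
  expect_error(average_repeats(c(10, 11, NA)), "three")
})

test_that("relative change is signed percent versus baseline", {
  expect_equal(relative_change(8.29, 10.3), -19.5, tolerance = 2e-3)
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(12, 10), 20)
  expect_error(relative_change(8, 0), "positive")
})

test_that("cumulative deficits and adequacy follow their definitions", {
  eq <- cumulative_deficit(c(25, 25, 25), c(25, 25, 25))
  expect_equal(eq$deficit, 0)
  expect_equal(eq$adequacy_pct, 100)
  part <- cumulative_deficit(rep(100, 10), rep(62.6, 10))
  expect_equal(part$adequacy_pct, 62.6)
  expect_equal(cumulative_deficit(c(25, 25), c(20, 15))$deficit, 15)
  expect_error(cumulative_deficit(c(25, 25), c(20, -1)), "negative")
})

make_cohort_tables <- function() {
  grid <- expand.grid(
    patient_id = c("P1", "P2"), side = c("L", "R"),
    day = c(0, 3, 7, 10), stringsAsFactors = FALSE
  )
  grid$muscle <- "RFM"
  thick <- ifelse(grid$day == 0, 10, 10 * (1 - grid$day / 100))
  us <- data.frame(grid, rep1 = thick, rep2 = thick, rep3 = thick)
  clinical <- data.frame(
    patient_id = c("P1", "P2"), age = c(50, 70), sex = c(0, 1),
    msofa = c(4, 6), calorie_deficit = c(1000, 2000),
    protein_deficit = c(100, 150)
  )
  features <- expand.grid(
    patient_id = c("P1", "P2"), side = c("L", "R"),
    stringsAsFactors = FALSE
  )
  features$pct_active <- c(0.5, 1.5, 2.5, 3.5)
  features$overall_intensity_g <- 0.03
  features$ab_intensity_logmean <- -1.4
  features$ab_duration_logmean <- 2.7
  features$ab_intensity_logsd <- 0.4
  features$ab_duration_logsd <- 0.6
  list(us = us, clinical = clinical, features = features)
}

test_that("the analysis table has one row per leg-day with faithful joins", {
  tb <- make_cohort_tables()
  tab <- build_analysis_table(tb$us, tb$clinical, tb$features)
  expect_equal(nrow(tab), 12) # 2 patients x 2 legs x 3 days
  expect_equal(sort(unique(tab$day)), c(3, 7, 10))
  expect_equal(
    tab$atrophy_pct[tab$day == 10],
    rep(-10, 4)
  )
  # join fidelity: the feature value lands unchanged on every row
  row <- tab[tab$patient_id == "P2" & tab$side == "L" & tab$day == 7, ]
  f <- tb$features
  expect_equal(
    row$pct_active,
    f$pct_active[f$patient_id == "P2" & f$side == "L"]
  )
  expect_equal(attr(tab, "audit")$n_candidate, 12)
  expect_equal(attr(tab, "audit")$n_rows, 12)
})

test_that("legs without a baseline scan are dropped and accounted for", {
  tb <- make_cohort_tables()
  us <- tb$us[!(tb$us$patient_id == "P1" & tb$us$side == "L" & tb$us$day == 0), ]
  tab <- build_analysis_table(us, tb$clinical, tb$features)
  expect_equal(nrow(tab), 9)
  audit <- attr(tab, "audit")
  expect_equal(audit$n_dropped_no_baseline, 3)
  expect_equal(audit$n_candidate - audit$n_dropped_no_baseline -
    audit$n_dropped_incomplete, audit$n_rows)
})

test_that("duplicate measurements error and input order does not matter", {
  tb <- make_cohort_tables()
  expect_error(
    build_analysis_table(rbind(tb$us, tb$us[1, ]), tb$clinical, tb$features),
    "duplicate"
  )
  set.seed(1)
  shuffled <- build_analysis_table(
    tb$us[sample(nrow(tb$us)), ],
    tb$clinical[2:1, ], tb$features[sample(4), ]
  )
  expect_equal(
    shuffled,
    build_analysis_table(tb$us, tb$clinical, tb$features),
    ignore_attr = TRUE
  )
})
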