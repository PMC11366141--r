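#' Linear model for temporalis-muscle atrophy
#'
#' The temporalis muscle (TM) is unaffected by leg movement, so a model
#' of day-10 TM atrophy on the demographic, clinical and nutritional
#' covariates plus `pct_active` acts as a negative control: the
#' `pct_active` coefficient is expected to be non-contributory (its
#' confidence interval covering zero). Ordinary least squares on
#' complete rows; a rank-deficient design is an error naming the aliased
#' columns.
#'
#' @param data data frame with the outcome and covariates.
#' @param outcome_col outcome column (default `"atrophy_pct"`).
#' @param covariates covariate columns (default the clinical predictor
#'   set plus `pct_active`).
#' @param level confidence level (default 0.95).
#' @return object of class `ols_fit`: the `lm` fit, a coefficient table
#'   with confidence intervals, and `pct_active_ci` (that row of the
#'   table, reported explicitly as the negative-control check).
#' @export
fit_ols_tm <- function(data, outcome_col = "atrophy_pct",
                       covariates = c(clinical_predictors(), "pct_active"),
                       level = 0.95) {
  covariates <- setdiff(covariates, "baseline_rfm_mm")
  if ("baseline_tm_mm" %in% names(data) &&
    !("baseline_tm_mm" %in% covariates)) {
    covariates <- c(covariates, "baseline_tm_mm")
  }
  covariates <- intersect(covariates, names(data))
  stopifnot(outcome_col %in% names(data), length(covariates) >= 1)
  use <- stats::complete.cases(data[, c(outcome_col, covariates)])
  d <- data[use, , drop = FALSE]
  if (nrow(d) <= length(covariates) + 1) {
    stop("fewer complete rows than model parameters: design is ",
      "rank-deficient",
      call. = FALSE
    )
  }
  fml <- stats::as.formula(paste(
    outcome_col, "~",
    paste(covariates, collapse = " + ")
  ))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop(
      "rank-deficient design; aliased column(s): ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
      call. = FALSE
    )
  }
  ci <- stats::confint(fit, level = level)
  tab <- data.frame(
    term = names(stats::coef(fit)),
    estimate = unname(stats::coef(fit)),
    lower = ci[, 1], upper = ci[, 2],
    p = summary(fit)$coefficients[, 4]
  )
  rownames(tab) <- NULL
  structure(
    list(
      fit = fit, coefficients = tab,
      pct_active_ci = tab[tab$term == "pct_active", , drop = FALSE],
      n = nrow(d)
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d\n", x$n))
  print(x$coefficients, digits = 3)
  if (nrow(x$pct_active_ci)) {
    covers0 <- x$pct_active_ci$lower <= 0 && x$pct_active_ci$upper >= 0
    cat(sprintf(
      "pct_active CI [%.3f, %.3f] %s 0\n",
      x$pct_active_ci$lower, x$pct_active_ci$upper,
      if (covers0) "covers" else "excludes"
    ))
  }
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value — the appropriate variant for the
#' very unbalanced healthy-control versus patient comparison (n = 3 vs
#' n = 53 in the emulated cohort). Implemented from the textbook
#' formulas; the degenerate case of zero variance in both groups with
#' equal means returns `t = 0, p = 1` by convention.
#'
#' @param group_a,group_b numeric vectors, each of length at least 2.
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
#' @examples
#' welch_ttest(c(1, 2, 3), c(2, 3, 4, 5))
welch_ttest <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  ma <- mean(group_a)
  mb <- mean(group_b)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(list(t = 0, df = na + nb - 2, p = 1, mean_a = ma, mean_b = mb))
    }
    stop("zero variance in both groups with unequal means: ",
      "t statistic undefined",
      call. = FALSE
    )
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}
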