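#' Fit training-set standardization and apply it elsewhere
#'
#' Z-score constants (per-column mean and SD) are computed on the
#' training portion only and reused unchanged on validation or test
#' data, so no information about held-out outcomes or predictor scales
#' leaks across the split.
#'
#' @param x numeric matrix or data frame (training predictors).
#' @return `zscore_fit()`: list with `center`, `scale` and the scaled
#'   training matrix `x`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale == 0)) {
    stop(
      "constant column(s) cannot be standardized: ",
      paste(colnames(x)[scale == 0], collapse = ", "),
      call. = FALSE
    )
  }
  list(center = center, scale = scale, x = sweep(sweep(x, 2, center), 2, scale, "/"))
}

#' @rdname zscore_fit
#' @param zs a `zscore_fit()` result.
#' @param newx matrix to standardize with the stored constants.
#' @export
zscore_apply <- function(zs, newx) {
  newx <- as.matrix(newx)[, names(zs$center), drop = FALSE]
  sweep(sweep(newx, 2, zs$center), 2, zs$scale, "/")
}

#' Held-out performance metrics
#'
#' Mean squared error, its square root, mean absolute error, and
#' R-squared computed as the squared Pearson correlation between
#' predicted and actual values (so a constant offset in the predictions
#' does not reduce it). With constant predictions the correlation is
#' undefined and `r2` is `NA` with a flag.
#'
#' @param actual,predicted numeric vectors of equal length.
#' @return object of class `metric_report`: list with `mse`, `rmse`,
#'   `mae`, `r2`, `r2_defined`, `n`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  err <- actual - predicted
  mse <- mean(err^2)
  r2_defined <- stats::sd(predicted) > 0 && stats::sd(actual) > 0
  r2 <- if (r2_defined) stats::cor(actual, predicted)^2 else NA_real_
  structure(
    list(
      mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
      r2 = r2, r2_defined = r2_defined, n = length(actual)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "MSE %.3f | RMSE %.3f | MAE %.3f | R2 %s (n = %d)\n",
    x$mse, x$rmse, x$mae,
    if (x$r2_defined) sprintf("%.3f", x$r2) else "undefined", x$n
  ))
  invisible(x)
}

#' Standardized effect expressed relative to a reference level
#'
#' A standardized coefficient of `beta` percentage points of atrophy per
#' SD of a predictor can be read against the cohort's mean baseline
#' thickness: `100 * |beta| / reference` is the coefficient as a percent
#' of that reference — e.g. a -5.1 point effect against a 10.3 mm mean
#' baseline is a 49.5% relative effect, and +1.6 against the same
#' reference is 15.5%.
#'
#' @param beta standardized coefficient (percentage points per SD).
#' @param reference reference level (e.g. mean baseline thickness, mm).
#' @return percent relative effect (non-negative).
#' @export
relative_effect_size <- function(beta, reference) {
  stopifnot(reference > 0)
  100 * abs(beta) / reference
}
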