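#' Variance inflation factors and iterative pruning
#'
#' `vif_values()` computes, for every column, `1 / (1 - R^2)` from the
#' ordinary least-squares regression of that column on all the others
#' (with intercept). `vif_filter()` iteratively removes the column with
#' the largest VIF while any VIF exceeds the threshold, logging the
#' removal order — the standard multicollinearity screen applied before
#' standardization and penalized fitting.
#'
#' @param x numeric matrix or data frame of candidate predictors
#'   (at least two columns, none constant).
#' @return `vif_values()`: named numeric vector of VIFs.
#' @export
vif_values <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant column(s): ",
      paste(colnames(x)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    r2 <- min(r2, 1 - 1e-12)
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(x))
}

#' @rdname vif_values
#' @param threshold removal threshold (default 5).
#' @return `vif_filter()`: list with `x` (the reduced matrix), `removed`
#'   (data frame logging variable, VIF at removal, and step), and `vif`
#'   (final VIFs of the retained columns).
#' @export
vif_filter <- function(x, threshold = 5) {
  x <- as.matrix(x)
  removed <- data.frame(
    variable = character(0), vif = numeric(0), step = integer(0)
  )
  step <- 0L
  while (ncol(x) >= 2) {
    v <- vif_values(x)
    if (max(v) <= threshold) break
    step <- step + 1L
    worst <- which.max(v)
    removed <- rbind(removed, data.frame(
      variable = names(v)[worst], vif = unname(v[worst]), step = step
    ))
    x <- x[, -worst, drop = FALSE]
  }
  list(
    x = x, removed = removed,
    vif = if (ncol(x) >= 2) vif_values(x) else stats::setNames(1, colnames(x))
  )
}
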