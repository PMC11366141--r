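#' BCa interval endpoints from a bootstrap sample
#'
#' Bias-corrected and accelerated endpoints: with bias-correction `z0`
#' and acceleration `a`, the interval takes the bootstrap quantiles at
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha)))`. With
#' `z0 = a = 0` this reduces exactly to the percentile interval.
#'
#' @param thetas bootstrap replicates of one statistic.
#' @param theta_hat point estimate.
#' @param z0,a bias correction and acceleration; estimated from
#'   `thetas` / `jack` when `NULL`.
#' @param jack jackknife replicates (needed to estimate `a`).
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `z0`, `a`, `degenerate`.
#' @export
bca_interval <- function(thetas, theta_hat, z0 = NULL, a = NULL,
                         jack = NULL, level = 0.95) {
  alpha <- (1 - level) / 2
  if (length(unique(thetas)) == 1) {
    return(list(
      lower = thetas[1], upper = thetas[1],
      z0 = NA_real_, a = NA_real_, degenerate = TRUE
    ))
  }
  if (is.null(z0)) {
    prop <- (sum(thetas < theta_hat) + 0.5 * sum(thetas == theta_hat)) /
      length(thetas)
    prop <- min(max(prop, 1 / (2 * length(thetas))), 1 - 1 / (2 * length(thetas)))
    z0 <- stats::qnorm(prop)
  }
  if (is.null(a)) {
    if (is.null(jack) || length(unique(jack)) == 1) {
      a <- 0
    } else {
      dev <- mean(jack) - jack
      a <- sum(dev^3) / (6 * sum(dev^2)^1.5)
    }
  }
  zl <- stats::qnorm(alpha)
  zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  qq <- stats::quantile(thetas, c(a1, a2), names = FALSE, type = 7)
  list(lower = qq[1], upper = qq[2], z0 = z0, a = a, degenerate = FALSE)
}

#' Cluster (patient) BCa bootstrap for the penalized mixed model
#'
#' Resamples patients — not rows — with replacement, refits
#' [fit_lmm_lasso()] at the fixed penalty on each resample, and forms
#' 95% BCa intervals per coefficient. The bias correction comes from the
#' share of bootstrap coefficients below the point estimate; the
#' acceleration from the jackknife over patients. Resampling whole
#' patients keeps the within-patient correlation structure intact, which
#' row-level resampling would break. A coefficient that is shrunk to the
#' same value (typically exactly zero) in every resample yields a
#' degenerate interval and is flagged.
#'
#' @inheritParams fit_lmm_lasso
#' @param n_resamples bootstrap resamples (study default 10000;
#'   scale down for quick runs).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return object of class `bootstrap_ci`: data frame `intervals` with
#'   columns `term`, `estimate`, `lower`, `upper`, `z0`, `a`,
#'   `degenerate`, plus `n_resamples` and the bootstrap coefficient
#'   matrix `replicates`.
#' @export
bootstrap_bca <- function(x, y, cluster, lambda, n_resamples = 10000,
                          seed = 1, penalized = NULL, level = 0.95,
                          control = lasso_lmm_control()) {
  stopifnot(n_resamples >= 100)
  x <- as.matrix(x)
  cluster <- as.character(cluster)
  patients <- sort(unique(cluster))
  np <- length(patients)
  rows_of <- split(seq_along(cluster), cluster)

  point <- fit_lmm_lasso(x, y, cluster, lambda,
    penalized = penalized, control = control
  )
  init <- list(beta = point$coefficients, gamma = point$gamma)
  p <- length(point$coefficients)

  refit <- function(pat_sample) {
    idx <- unlist(rows_of[pat_sample], use.names = FALSE)
    # resampled copies of the same patient are distinct clusters
    cl <- rep(seq_along(pat_sample), lengths(rows_of[pat_sample]))
    f <- fit_lmm_lasso(x[idx, , drop = FALSE], y[idx], cl, lambda,
      penalized = penalized, init = init, control = control
    )
    f$coefficients
  }

  set.seed(seed)
  boot_mat <- matrix(NA_real_, n_resamples, p)
  for (b in seq_len(n_resamples)) {
    boot_mat[b, ] <- refit(sample(patients, np, replace = TRUE))
  }
  jack_mat <- t(vapply(
    seq_len(np),
    function(i) refit(patients[-i]), numeric(p)
  ))
  colnames(boot_mat) <- colnames(jack_mat) <- names(point$coefficients)

  ints <- do.call(rbind, lapply(seq_len(p), function(j) {
    ci <- bca_interval(boot_mat[, j], point$coefficients[j],
      jack = jack_mat[, j], level = level
    )
    data.frame(
      term = names(point$coefficients)[j],
      estimate = unname(point$coefficients[j]),
      lower = ci$lower, upper = ci$upper,
      z0 = ci$z0, a = ci$a, degenerate = ci$degenerate
    )
  }))
  rownames(ints) <- NULL
  structure(
    list(
      intervals = ints, n_resamples = n_resamples,
      replicates = boot_mat, level = level, lambda = lambda
    ),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_ci> %d patient-cluster resamples, %.0f%% BCa\n",
    x$n_resamples, 100 * x$level
  ))
  print(x$intervals[, c("term", "estimate", "lower", "upper", "degenerate")],
    digits = 3
  )
  invisible(x)
}
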