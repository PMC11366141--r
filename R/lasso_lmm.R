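#' Control parameters for the penalized mixed-model solver
#'
#' @param max_iter maximum number of outer alternations between the
#'   coordinate-descent and variance steps.
#' @param tol convergence tolerance on the penalized objective change.
#' @param cd_tol coordinate-descent tolerance on the largest coefficient
#'   move within a sweep.
#' @param cd_max_sweeps cap on coordinate-descent sweeps per alternation.
#' @param gamma_max upper bound of the variance-ratio search interval.
#' @return list of control values.
#' @export
lasso_lmm_control <- function(max_iter = 500, tol = 1e-8, cd_tol = 1e-10,
                              cd_max_sweeps = 10000, gamma_max = 1e7) {
  list(
    max_iter = max_iter, tol = tol, cd_tol = cd_tol,
    cd_max_sweeps = cd_max_sweeps, gamma_max = gamma_max
  )
}

#' L1-penalized linear mixed model with patient random intercepts
#'
#' Fits the Gaussian mixed model `y = b0 + X beta + Z u + e` with one
#' random intercept per cluster (patient), minimizing the penalized
#' negative log-likelihood
#' `0.5 * [log|V| + (y - Xb)' V^{-1} (y - Xb)] + lambda * sum |beta_j|`
#' over the penalized coefficients (the intercept and the variance
#' components are never penalized), where
#' `V = sigma_e^2 I + sigma_b^2 Z Z'`. The algorithm alternates
#' (i) cyclic coordinate descent with soft-thresholding on the
#' GLS-whitened fixed-effects problem and (ii) a profile
#' maximum-likelihood update of the variance components given the
#' current coefficients. Both steps decrease the objective, so the
#' objective trace is non-increasing; zeros in the solution are exact.
#'
#' At `lambda = 0` the fit coincides with the unpenalized ML linear
#' mixed model; at very large `lambda` all penalized coefficients are
#' exactly zero and the intercept equals the GLS-weighted outcome mean.
#'
#' @param x numeric predictor matrix (no intercept column; one is added
#'   and left unpenalized).
#' @param y numeric outcome vector.
#' @param cluster cluster (patient) identifier, one per row of `x`.
#' @param lambda penalty weight, `>= 0`.
#' @param penalized logical vector, one per column of `x` (default all
#'   `TRUE`).
#' @param init optional warm start: list with `beta` (length
#'   `ncol(x) + 1`, intercept first) and `gamma` (variance ratio
#'   `sigma_b^2 / sigma_e^2`).
#' @param fix_variance optional list `list(sigma_b =, sigma_e =)`; when
#'   supplied the variance components are held fixed (used by the
#'   oracle cross-checks).
#' @param control see [lasso_lmm_control()].
#' @return object of class `lasso_lmm`: coefficients (named, intercept
#'   first), `sigma_b`, `sigma_e`, `lambda`, `objective`,
#'   `objective_trace`, `n_iter`, `converged` (non-convergence flags the
#'   fit rather than erroring).
#' @export
fit_lmm_lasso <- function(x, y, cluster, lambda,
                          penalized = NULL, init = NULL,
                          fix_variance = NULL,
                          control = lasso_lmm_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y), length(cluster) == length(y), lambda >= 0)
  cl <- as.integer(factor(cluster)) - 1L
  if (length(unique(cl)) < 2 && is.null(fix_variance)) {
    stop("need at least two clusters to estimate a random intercept",
      call. = FALSE
    )
  }
  if (is.null(penalized)) penalized <- rep(TRUE, ncol(x))
  stopifnot(length(penalized) == ncol(x))

  X <- cbind(`(Intercept)` = 1, x)
  pen <- c(0, as.numeric(penalized))
  beta0 <- if (!is.null(init$beta)) init$beta else c(mean(y), rep(0, ncol(x)))
  gamma0 <- if (!is.null(init$gamma)) init$gamma else 0.5
  fixv <- !is.null(fix_variance)
  if (fixv) {
    sige2 <- fix_variance$sigma_e^2
    gamma0 <- fix_variance$sigma_b^2 / sige2
  } else {
    sige2 <- stats::var(y)
  }

  res <- .lassolmm_fit_cpp(
    X, as.numeric(y), as.integer(cl), pen, lambda,
    as.numeric(beta0), gamma0, sige2, fixv,
    control$max_iter, control$tol, control$cd_tol,
    control$cd_max_sweeps, control$gamma_max
  )
  if (!res$converged) {
    warning("fit_lmm_lasso did not converge in ", control$max_iter,
      " alternations (lambda = ", signif(lambda, 3), ")",
      call. = FALSE
    )
  }
  structure(
    list(
      coefficients = stats::setNames(as.numeric(res$beta), colnames(X)),
      sigma_b = res$sigma_b, sigma_e = res$sigma_e, gamma = res$gamma,
      lambda = lambda, objective = res$objective,
      objective_trace = as.numeric(res$trace),
      n_iter = res$n_iter, converged = res$converged,
      penalized = stats::setNames(pen > 0.5, colnames(X)),
      xnames = colnames(x)
    ),
    class = "lasso_lmm"
  )
}

#' @export
print.lasso_lmm <- function(x, ...) {
  cat(sprintf(
    "<lasso_lmm> lambda = %.4g, sigma_b = %.3f, sigma_e = %.3f, %s\n",
    x$lambda, x$sigma_b, x$sigma_e,
    if (x$converged) "converged" else "NOT converged"
  ))
  nz <- x$coefficients[x$coefficients != 0]
  print(round(nz, 4))
  invisible(x)
}

#' Predict from a penalized mixed-model fit
#'
#' Predictions use the fixed effects only (random effect set to 0, the
#' population mean), the convention for patients unseen at training
#' time.
#'
#' @param object a `lasso_lmm` fit.
#' @param newx predictor matrix with the columns the model was fit on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lasso_lmm <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx)) && all(object$xnames %in% colnames(newx))) {
    newx <- newx[, object$xnames, drop = FALSE]
  }
  stopifnot(ncol(newx) == length(object$coefficients) - 1)
  drop(cbind(1, newx) %*% object$coefficients)
}

#' Penalty grid from the data
#'
#' Computes `lambda_max`, the smallest penalty that shrinks every
#' penalized coefficient to exactly zero (from the whitened gradient at
#' the intercept-only fit), and returns `n` log-spaced values from
#' `lambda_max` down to `lambda_max * min_ratio`, sorted increasing.
#'
#' @inheritParams fit_lmm_lasso
#' @param n grid size (default 50).
#' @param min_ratio smallest grid value relative to `lambda_max`
#'   (default 1/1000).
#' @return increasing numeric vector of penalties.
#' @export
lambda_grid <- function(x, y, cluster, penalized = NULL, n = 50,
                        min_ratio = 1 / 1000) {
  x <- as.matrix(x)
  null_fit <- fit_lmm_lasso(x, y, cluster,
    lambda = 1e10, penalized = penalized
  )
  # whiten at the null fit's variance components and take the largest
  # absolute gradient of the quadratic loss at beta = 0
  cl <- as.integer(factor(cluster))
  ni <- tabulate(cl)
  d <- 1 - 1 / sqrt(1 + ni * null_fit$gamma)
  w <- (d / ni)[cl]
  X <- cbind(1, x)
  Sx <- rowsum(X, cl)
  Sy <- rowsum(as.numeric(y), cl)
  Xt <- (X - w * Sx[cl, , drop = FALSE]) / null_fit$sigma_e
  yt <- (y - w * Sy[cl]) / null_fit$sigma_e
  r <- yt - drop(Xt %*% null_fit$coefficients)
  pen_cols <- which(null_fit$penalized) # includes the intercept as FALSE
  lam_max <- max(abs(crossprod(Xt[, pen_cols, drop = FALSE], r)))
  exp(seq(log(lam_max * min_ratio), log(lam_max), length.out = n))
}
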