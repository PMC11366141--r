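#' Nested cross-validation for the penalty weight
#'
#' Tunes the L1 penalty of [fit_lmm_lasso()] with patient-grouped nested
#' cross-validation: the training patients are partitioned into
#' `outer_k` folds; within each outer-training set an inner `inner_k`-fold
#' loop computes the mean validation MSE over the penalty grid
#' (predictions for unseen patients use a random effect of 0) and picks
#' the penalty minimizing it, ties broken toward the larger (more
#' parsimonious) value. The final penalty is the arithmetic mean of the
#' outer-fold optima, and the final model is refit on all supplied data
#' at that penalty. Fold assignment is keyed on the sorted patient
#' identifiers, so permuting the input rows patient-wise does not change
#' the result.
#'
#' @inheritParams fit_lmm_lasso
#' @param lambda_grid increasing vector of positive penalties; computed
#'   from the data via [lambda_grid()] when `NULL`.
#' @param outer_k,inner_k fold counts (defaults 4 and 2).
#' @param seed integer seed for the fold assignments.
#' @return object of class `nested_cv`: `lambda_opt` (per outer fold),
#'   `inner_mse` (folds x grid matrix of inner-loop mean MSE curves),
#'   `outer_mse` (validation MSE of each outer fold at its optimum),
#'   `lambda_final`, `fit` (final refit), `lambda_grid`, `folds`.
#' @export
nested_cv <- function(x, y, cluster, lambda_grid = NULL,
                      outer_k = 4, inner_k = 2, seed = 1,
                      penalized = NULL, control = lasso_lmm_control()) {
  x <- as.matrix(x)
  cluster <- as.character(cluster)
  patients <- sort(unique(cluster))
  if (length(patients) < outer_k) {
    stop("need at least as many patients as outer folds", call. = FALSE)
  }
  if (is.null(lambda_grid)) {
    lambda_grid <- lambda_grid(x, y, cluster, penalized = penalized)
  }
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0) ||
    is.unsorted(lambda_grid)) {
    stop("lambda_grid must be a non-empty increasing positive vector",
      call. = FALSE
    )
  }

  set.seed(seed)
  outer_fold <- stats::setNames(
    sample(rep(seq_len(outer_k), length.out = length(patients))), patients
  )

  path_mse <- function(xtr, ytr, cltr, xva, yva) {
    # warm-started descent along the grid from the largest penalty down
    mse <- numeric(length(lambda_grid))
    init <- NULL
    for (i in rev(seq_along(lambda_grid))) {
      f <- fit_lmm_lasso(xtr, ytr, cltr, lambda_grid[i],
        penalized = penalized, init = init, control = control
      )
      init <- list(beta = f$coefficients, gamma = f$gamma)
      mse[i] <- mean((yva - predict(f, xva))^2)
    }
    mse
  }

  inner_mse <- matrix(NA_real_, outer_k, length(lambda_grid))
  lambda_opt <- numeric(outer_k)
  outer_mse <- numeric(outer_k)
  for (k in seq_len(outer_k)) {
    tr_pat <- patients[outer_fold != k]
    va_pat <- patients[outer_fold == k]
    inner_fold <- stats::setNames(
      sample(rep(seq_len(inner_k), length.out = length(tr_pat))), tr_pat
    )
    mse_k <- matrix(NA_real_, inner_k, length(lambda_grid))
    for (j in seq_len(inner_k)) {
      fit_pat <- tr_pat[inner_fold != j]
      val_pat <- tr_pat[inner_fold == j]
      ridx <- cluster %in% fit_pat
      vidx <- cluster %in% val_pat
      mse_k[j, ] <- path_mse(
        x[ridx, , drop = FALSE], y[ridx], cluster[ridx],
        x[vidx, , drop = FALSE], y[vidx]
      )
    }
    inner_mse[k, ] <- colMeans(mse_k)
    best <- max(lambda_grid[inner_mse[k, ] == min(inner_mse[k, ])])
    lambda_opt[k] <- best
    tridx <- cluster %in% tr_pat
    vaidx <- cluster %in% va_pat
    fk <- fit_lmm_lasso(x[tridx, , drop = FALSE], y[tridx], cluster[tridx],
      best,
      penalized = penalized, control = control
    )
    outer_mse[k] <- mean((y[vaidx] - predict(fk, x[vaidx, , drop = FALSE]))^2)
  }

  lambda_final <- mean(lambda_opt)
  final <- fit_lmm_lasso(x, y, cluster, lambda_final,
    penalized = penalized, control = control
  )
  structure(
    list(
      lambda_opt = lambda_opt, inner_mse = inner_mse,
      outer_mse = outer_mse, lambda_final = lambda_final,
      fit = final, lambda_grid = lambda_grid,
      folds = outer_fold
    ),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "<nested_cv> %d outer folds; per-fold optimal lambda: %s\n",
    length(x$lambda_opt), paste(signif(x$lambda_opt, 3), collapse = ", ")
  ))
  cat(sprintf("final lambda (mean of optima): %.4g\n", x$lambda_final))
  print(x$fit)
  invisible(x)
}
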