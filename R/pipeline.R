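#' Pipeline configuration
#'
#' Collects every stage parameter with the study constants as defaults:
#' 5 s windows, 0.2 Hz 4th-order high-pass, 0.135 g bout threshold,
#' 10 Hz target rate, VIF threshold 5, 80/20 grouped stratified split,
#' 4 outer / 2 inner cross-validation folds. Overrides are recorded in
#' the run manifest.
#'
#' @param sim a [sim_config()] block for the synthetic stages.
#' @param window_s,cutoff_hz,filter_order,threshold_g,target_hz feature
#'   parameters.
#' @param test_frac,outer_k,inner_k,vif_threshold,n_lambda,n_resamples
#'   modeling parameters.
#' @param days follow-up days pooled into the analysis table
#'   (default `c(3, 7, 10)`).
#' @param with_movement_features if `FALSE`, the movement biomarkers are
#'   dropped from the predictor set (the comparison model).
#' @param seed integer; the single seed from which every stage's
#'   randomness is derived.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window_s = 5, cutoff_hz = 0.2, filter_order = 4,
                            threshold_g = 0.135, target_hz = 10,
                            test_frac = 0.2, outer_k = 4, inner_k = 2,
                            vif_threshold = 5, n_lambda = 50,
                            n_resamples = 1000, days = c(3, 7, 10),
                            with_movement_features = TRUE, seed = 1) {
  cfg <- list(
    sim = sim, window_s = window_s, cutoff_hz = cutoff_hz,
    filter_order = filter_order, threshold_g = threshold_g,
    target_hz = target_hz, test_frac = test_frac, outer_k = outer_k,
    inner_k = inner_k, vif_threshold = vif_threshold, n_lambda = n_lambda,
    n_resamples = n_resamples, days = days,
    with_movement_features = with_movement_features, seed = seed
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), "preset")])
  x$sim <- NULL
  cfg <- do.call(pipeline_config, c(list(sim = sim), x))
  cfg
}

#' Fit the atrophy prediction model end to end
#'
#' The modeling stage as one call: variance-inflation pruning of the
#' candidate predictors, grouped outcome-stratified 80/20 split,
#' training-set z-scoring (constants reused on the test set), nested
#' cross-validation of the L1 penalty, final penalized mixed-model fit,
#' and held-out evaluation with fixed-effects predictions.
#'
#' @param table analysis table from [build_analysis_table()] (or
#'   [simulate_analysis_table()]).
#' @param predictors candidate predictor columns; defaults to the
#'   clinical plus movement sets, with the collinear extras
#'   (`ab_per_hour`, `sofa`) added when present so the VIF filter can
#'   act on them.
#' @param with_movement_features drop the movement biomarkers when
#'   `FALSE`.
#' @param test_frac,vif_threshold,outer_k,inner_k,n_lambda,seed see
#'   [pipeline_config()].
#' @param control solver control, see [lasso_lmm_control()].
#' @return object of class `atrophy_model`: the VIF log, split, nested
#'   CV result, final fit, standardized coefficient vector, and train /
#'   test [evaluate_predictions()] reports.
#' @export
fit_atrophy_model <- function(table, predictors = NULL,
                              with_movement_features = TRUE,
                              test_frac = 0.2, vif_threshold = 5,
                              outer_k = 4, inner_k = 2, n_lambda = 50,
                              seed = 1, control = lasso_lmm_control()) {
  if (is.null(predictors)) {
    predictors <- c(clinical_predictors(), movement_predictors())
    extras <- intersect(c("ab_per_hour", "sofa"), names(table))
    predictors <- c(predictors, extras)
  }
  if (!with_movement_features) {
    predictors <- setdiff(predictors, c(movement_predictors(), "ab_per_hour"))
  }
  predictors <- intersect(predictors, names(table))
  stopifnot(length(predictors) >= 2)

  vif <- vif_filter(as.matrix(table[, predictors, drop = FALSE]),
    threshold = vif_threshold
  )
  kept <- colnames(vif$x)

  split <- grouped_stratified_split(table,
    test_frac = test_frac, seed = seed
  )
  zs <- zscore_fit(split$train[, kept, drop = FALSE])
  x_train <- zs$x
  x_test <- zscore_apply(zs, split$test[, kept, drop = FALSE])
  y_train <- split$train$atrophy_pct
  y_test <- split$test$atrophy_pct

  cv <- nested_cv(x_train, y_train, split$train$patient_id,
    lambda_grid = lambda_grid(x_train, y_train, split$train$patient_id,
      n = n_lambda
    ),
    outer_k = outer_k, inner_k = inner_k, seed = seed, control = control
  )
  pred_test <- predict(cv$fit, x_test)
  pred_train <- predict(cv$fit, x_train)
  structure(
    list(
      vif = vif, kept_predictors = kept, split = split,
      standardization = zs[c("center", "scale")], cv = cv, fit = cv$fit,
      coefficients = cv$fit$coefficients,
      metrics_test = evaluate_predictions(y_test, pred_test),
      metrics_train = evaluate_predictions(y_train, pred_train),
      predictions = data.frame(
        patient_id = c(split$train$patient_id, split$test$patient_id),
        set = rep(c("train", "test"), c(nrow(split$train), nrow(split$test))),
        actual = c(y_train, y_test),
        predicted = c(pred_train, pred_test)
      ),
      with_movement_features = with_movement_features,
      seed = seed
    ),
    class = "atrophy_model"
  )
}

#' @export
print.atrophy_model <- function(x, ...) {
  cat(sprintf(
    "<atrophy_model> %s movement features; %d predictors after VIF\n",
    if (x$with_movement_features) "with" else "without",
    length(x$kept_predictors)
  ))
  if (nrow(x$vif$removed)) {
    cat(
      "VIF-removed:",
      paste(x$vif$removed$variable, collapse = ", "), "\n"
    )
  }
  cat(sprintf("lambda (mean of outer optima): %.4g\n", x$cv$lambda_final))
  cat("test: ")
  print(x$metrics_test)
  invisible(x)
}

#' Run the full synthetic pipeline into a directory
#'
#' Chains the stages: simulate a cohort (and a small set of raw
#' accelerometer recordings, processed through the feature pipeline as a
#' QC check), build the analysis table, fit the atrophy model with and
#' without movement features, and write every stage output plus a
#' manifest (configuration, seed, package version, per-file checksums)
#' into `out_dir`. Rerunning with the same configuration reproduces all
#' outputs bitwise.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param n_demo_recordings number of legs for which raw recordings are
#'   simulated and pushed through the signal pipeline (default 2; the
#'   cohort's feature table itself is drawn from the feature laws).
#' @return the manifest, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         n_demo_recordings = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  # stage 1: cohort tables
  cohort <- simulate_cohort(config$sim)
  utils::write.csv(cohort$ultrasound, file.path(out_dir, "ultrasound.csv"),
    row.names = FALSE
  )
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
    row.names = FALSE
  )
  utils::write.csv(cohort$features, file.path(out_dir, "features.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      beta = as.list(cohort$truth$beta),
      intercept = cohort$truth$intercept
    ),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  # stage 2: raw-recording QC demo through the signal pipeline
  demo <- list()
  for (i in seq_len(n_demo_recordings)) {
    sim <- simulate_recording(config$sim,
      leg_id = sprintf("demo%02d", i), patient_id = sprintf("demoP%02d", i)
    )
    feats <- movement_features(sim$recording, sim$exclusions,
      threshold_g = config$threshold_g, window_s = config$window_s,
      cutoff_hz = config$cutoff_hz, order = config$filter_order,
      target_hz = config$target_hz
    )
    demo[[i]] <- data.frame(
      leg_id = sim$recording$leg_id,
      true_pct_active = sim$truth$pct_active,
      true_n_bouts = sim$truth$n_bouts, feats
    )
  }
  demo <- do.call(rbind, demo)
  utils::write.csv(demo, file.path(out_dir, "recording_qc.csv"),
    row.names = FALSE
  )

  # stage 3: analysis table
  tab <- build_analysis_table(cohort$ultrasound, cohort$clinical,
    cohort$features,
    days = config$days
  )
  utils::write.csv(tab, file.path(out_dir, "analysis_table.csv"),
    row.names = FALSE
  )

  # stage 4: models with and without movement features
  m_with <- fit_atrophy_model(tab,
    with_movement_features = TRUE,
    test_frac = config$test_frac, vif_threshold = config$vif_threshold,
    outer_k = config$outer_k, inner_k = config$inner_k,
    n_lambda = config$n_lambda, seed = config$seed
  )
  m_without <- fit_atrophy_model(tab,
    with_movement_features = FALSE,
    test_frac = config$test_frac, vif_threshold = config$vif_threshold,
    outer_k = config$outer_k, inner_k = config$inner_k,
    n_lambda = config$n_lambda, seed = config$seed
  )
  utils::write.csv(m_with$predictions,
    file.path(out_dir, "predicted_vs_actual.csv"),
    row.names = FALSE
  )
  report <- list(
    vif_removed = m_with$vif$removed,
    lambda_per_outer_fold = m_with$cv$lambda_opt,
    lambda_final = m_with$cv$lambda_final,
    coefficients = as.list(m_with$coefficients),
    metrics = list(
      with_movement = unclass(m_with$metrics_test)[c("mse", "rmse", "mae", "r2")],
      without_movement = unclass(m_without$metrics_test)[c("mse", "rmse", "mae", "r2")]
    ),
    audit = attr(tab, "audit")
  )
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  files <- c(
    "ultrasound.csv", "clinical.csv", "features.csv",
    "ground_truth.json", "recording_qc.csv", "analysis_table.csv",
    "predicted_vs_actual.csv", "model_report.json"
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("icumotion")),
    seed = config$seed,
    config = local({
      x <- unclass(config)
      x$sim <- unclass(x$sim)
      x
    }),
    checksums = vapply(
      files,
      function(f) unname(tools::md5sum(file.path(out_dir, f))), character(1)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
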