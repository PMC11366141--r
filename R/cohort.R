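#' Mean of the three repeated ultrasound measurements
#'
#' Muscle thickness at each site and day is measured three times; the
#' arithmetic mean of the repeats is carried forward. Missing repeats are
#' an error: no imputation is done anywhere in the pipeline.
#'
#' @param repeats numeric vector of exactly three positive thicknesses (mm).
#' @return the mean thickness (mm).
#' @export
average_repeats <- function(repeats) {
  if (length(repeats) != 3 || any(!is.finite(repeats))) {
    stop("exactly three finite repeated measurements are required ",
      "(no imputation)",
      call. = FALSE
    )
  }
  if (any(repeats <= 0)) {
    stop("thickness measurements must be positive", call. = FALSE)
  }
  mean(repeats)
}

#' Relative change in muscle thickness versus baseline
#'
#' Signed percent change, `100 * (day - day0) / day0`; atrophy is
#' negative.
#'
#' @param thickness_day_mm thickness at the follow-up day (mm).
#' @param thickness_day0_mm baseline (day 0) thickness (mm), positive.
#' @return percent change.
#' @export
#' @examples
#' relative_change(8.29, 10.3) # about -19.5
relative_change <- function(thickness_day_mm, thickness_day0_mm) {
  if (any(thickness_day0_mm <= 0)) {
    stop("baseline thickness must be positive", call. = FALSE)
  }
  100 * (thickness_day_mm - thickness_day0_mm) / thickness_day0_mm
}

#' Cumulative nutritional deficit and adequacy
#'
#' Sums `prescribed - administered` over days 1..`up_to_day` and reports
#' the percent adequacy `100 * sum(administered) / sum(prescribed)`.
#'
#' @param prescribed_daily,administered_daily equal-length daily series
#'   (kcal or g protein).
#' @param up_to_day last day included (default: whole series).
#' @return list with `deficit` and `adequacy_pct`.
#' @export
cumulative_deficit <- function(prescribed_daily, administered_daily,
                               up_to_day = length(prescribed_daily)) {
  if (length(prescribed_daily) != length(administered_daily)) {
    stop("prescribed and administered series must have equal length",
      call. = FALSE
    )
  }
  if (any(administered_daily < 0)) {
    stop("administered amounts cannot be negative", call. = FALSE)
  }
  stopifnot(up_to_day >= 1, up_to_day <= length(prescribed_daily))
  idx <- seq_len(up_to_day)
  p <- sum(prescribed_daily[idx])
  a <- sum(administered_daily[idx])
  list(deficit = p - a, adequacy_pct = 100 * a / p)
}

#' Candidate predictor sets
#'
#' The modeled predictor set is the study's 12 standardized variables:
#' six demographic/clinical/nutritional and six movement biomarkers.
#' `ab_per_hour` and the full SOFA score are carried in the tables as
#' collinear candidates and are expected to fall to the variance
#' inflation filter.
#'
#' @return character vector of column names.
#' @export
clinical_predictors <- function() {
  c(
    "age", "sex", "baseline_rfm_mm", "msofa",
    "calorie_deficit", "protein_deficit"
  )
}

#' @rdname clinical_predictors
#' @export
movement_predictors <- function() {
  c(
    "overall_intensity_g", "pct_active",
    "ab_intensity_logmean", "ab_duration_logmean",
    "ab_intensity_logsd", "ab_duration_logsd"
  )
}

#' Build the per-leg-observation analysis table
#'
#' Joins ultrasound-derived outcomes, patient-level clinical covariates
#' and leg-level movement features into one row per (leg, follow-up day).
#' The outcome is the percent change of mean muscle thickness versus the
#' same leg's day-0 scan; legs without a day-0 scan are dropped and
#' counted, as are rows missing the outcome or any modeled predictor
#' (no imputation). Input row order does not affect the result.
#'
#' @param ultrasound data frame with columns `patient_id`, `side`,
#'   `muscle`, `day`, `rep1`, `rep2`, `rep3`.
#' @param clinical data frame keyed by `patient_id` with the clinical
#'   covariates (see [clinical_predictors()], plus optional extras such as
#'   `sofa`).
#' @param features data frame keyed by (`patient_id`, `side`) with the
#'   movement features (see [movement_predictors()], plus optional extras
#'   such as `ab_per_hour` or `limb_group`).
#' @param days follow-up days to keep (default `c(3, 7, 10)`; use `10`
#'   for a day-10-only table).
#' @param muscle `"RFM"` (default) or `"TM"`.
#' @return data frame with identifier columns (`patient_id`, `leg_id`,
#'   `side`, `day`), the outcome `atrophy_pct`, the predictors, and any
#'   extra clinical/feature columns. An attribute `"audit"` carries the
#'   dropped-row accounting.
#' @export
build_analysis_table <- function(ultrasound, clinical, features,
                                 days = c(3, 7, 10), muscle = "RFM") {
  need_us <- c("patient_id", "side", "muscle", "day", "rep1", "rep2", "rep3")
  stopifnot(all(need_us %in% names(ultrasound)))
  key <- with(ultrasound, paste(patient_id, side, muscle, day))
  if (anyDuplicated(key)) {
    stop(
      "duplicate ultrasound measurement for: ",
      paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  if (!all(ultrasound$day %in% c(0, 3, 7, 10))) {
    stop("ultrasound days must be in {0, 3, 7, 10}", call. = FALSE)
  }

  us <- ultrasound[ultrasound$muscle == muscle, , drop = FALSE]
  us <- us[order(us$patient_id, us$side, us$day), , drop = FALSE]
  us$thickness_mm <- vapply(
    seq_len(nrow(us)),
    function(i) average_repeats(as.numeric(us[i, c("rep1", "rep2", "rep3")])),
    numeric(1)
  )

  base <- us[us$day == 0, c("patient_id", "side", "thickness_mm")]
  names(base)[3] <- "baseline_mm"
  fup <- us[us$day %in% days, , drop = FALSE]
  n_candidate <- nrow(fup)

  tab <- merge(fup, base, by = c("patient_id", "side"), all.x = TRUE)
  n_no_baseline <- sum(is.na(tab$baseline_mm))
  tab <- tab[!is.na(tab$baseline_mm), , drop = FALSE]
  tab$atrophy_pct <- relative_change(tab$thickness_mm, tab$baseline_mm)

  tab <- merge(tab, clinical, by = "patient_id", all.x = TRUE)
  tab <- merge(tab, features, by = c("patient_id", "side"), all.x = TRUE)
  if (muscle == "RFM" && !("baseline_rfm_mm" %in% names(tab))) {
    tab$baseline_rfm_mm <- tab$baseline_mm
  }

  predictors <- c(clinical_predictors(), movement_predictors())
  predictors <- intersect(predictors, names(tab))
  complete <- stats::complete.cases(tab[, c("atrophy_pct", predictors)])
  n_incomplete <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]

  tab$leg_id <- paste(tab$patient_id, tab$side, sep = "_")
  front <- c("patient_id", "leg_id", "side", "day", "atrophy_pct")
  tab <- tab[order(tab$patient_id, tab$side, tab$day),
    c(front, setdiff(names(tab), front)),
    drop = FALSE
  ]
  rownames(tab) <- NULL
  attr(tab, "audit") <- list(
    n_candidate = n_candidate,
    n_dropped_no_baseline = n_no_baseline,
    n_dropped_incomplete = n_incomplete,
    n_rows = nrow(tab)
  )
  stopifnot(n_candidate - n_no_baseline - n_incomplete == nrow(tab))
  tab
}
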