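#' Grouped, outcome-stratified train/test split
#'
#' Splits by patient, never by row: every observation of a patient
#' (both legs, all days) lands on the same side, so no information leaks
#' across the split through intra-patient correlation. Patients are
#' stratified by quantile bin of their mean outcome, and the test quota
#' is allocated across strata by largest remainder so the realized test
#' fraction is within one patient of the target. With too few patients
#' per stratum the split falls back to an unstratified grouped split
#' with a warning.
#'
#' @param data data frame containing the outcome and patient identifier.
#' @param patient_col,outcome_col column names (defaults `"patient_id"`,
#'   `"atrophy_pct"`).
#' @param test_frac fraction of patients assigned to the test set (0.2).
#' @param seed integer seed making the split reproducible.
#' @param n_strata number of outcome-quantile strata (default 4).
#' @return list with `train`, `test` (row subsets of `data`),
#'   `test_patients`, and `strata` (the per-patient stratum labels).
#' @export
grouped_stratified_split <- function(data, patient_col = "patient_id",
                                     outcome_col = "atrophy_pct",
                                     test_frac = 0.2, seed = 1,
                                     n_strata = 4) {
  stopifnot(
    patient_col %in% names(data), outcome_col %in% names(data),
    test_frac > 0, test_frac < 1
  )
  pat_mean <- tapply(data[[outcome_col]], data[[patient_col]], mean)
  patients <- sort(names(pat_mean))
  pat_mean <- pat_mean[patients]
  n_pat <- length(patients)
  if (n_pat < 5) stop("need at least 5 patients to split", call. = FALSE)

  qs <- unique(stats::quantile(pat_mean, probs = seq(0, 1, length.out = n_strata + 1)))
  strata <- as.integer(cut(pat_mean, qs, include.lowest = TRUE))
  if (min(table(strata)) < 2 || length(qs) < 3) {
    warning("too few patients per stratum; falling back to an ",
      "unstratified grouped split",
      call. = FALSE
    )
    strata <- rep(1L, n_pat)
  }

  target <- round(test_frac * n_pat)
  target <- min(max(target, 1), n_pat - 1)
  tab <- table(strata)
  quota_raw <- as.numeric(tab) * test_frac
  quota <- floor(quota_raw)
  short <- target - sum(quota)
  if (short > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1
  } else if (short < 0) {
    trim <- order(quota_raw - quota)[seq_len(-short)]
    quota[trim] <- pmax(quota[trim] - 1, 0)
  }

  set.seed(seed)
  test_patients <- unlist(lapply(seq_along(tab), function(s) {
    members <- patients[strata == as.integer(names(tab))[s]]
    if (quota[s] == 0) {
      return(character(0))
    }
    sample(members, min(quota[s], length(members)))
  }), use.names = FALSE)

  is_test <- data[[patient_col]] %in% test_patients
  list(
    train = data[!is_test, , drop = FALSE],
    test = data[is_test, , drop = FALSE],
    test_patients = sort(test_patients),
    strata = stats::setNames(strata, patients)
  )
}
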