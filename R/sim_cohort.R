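# log-normal parameters matching a target mean and SD
lnorm_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sigma2 <- log1p(cv2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

rnorm_trunc_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate a synthetic neuro-ICU cohort with known ground truth
#'
#' Generates the three raw tables the cohort builder consumes
#' (ultrasound repeats, clinical covariates, per-leg movement features)
#' together with the ground truth behind them. Movement features are
#' drawn directly from their configured laws (fast path); recordings for
#' individual legs can be produced separately with
#' [simulate_recording()].
#'
#' The outcome model plants the configured standardized effects: the
#' day-10 RFM change (%) is
#' `intercept + b1 * z(baseline RFM) + b2 * z(%active) + u_patient + e`,
#' with `z()` using the configured population moments, `u` the patient
#' random intercept (shared by both legs and all days) and `e` the
#' per-observation residual. The day-3/7 mean trajectory scales the
#' intercept by the configured fractions; covariate effects and the
#' random intercept enter fully at every day, so the pooled
#' repeated-observations model is correctly specified with constant
#' betas. Nuisance covariates (age, sex, mSOFA, deficits, the remaining
#' movement features) are drawn independent of the outcome. Two
#' deliberately collinear candidates are included: the full SOFA score
#' (tracks mSOFA plus a neurology component correlated with age) and
#' `ab_per_hour` (a near-deterministic function of %active and bout
#' duration), which the variance-inflation filter is expected to remove.
#'
#' Draw order (one seeded stream): patient clinical block, baseline
#' thicknesses, random intercepts, leg availability, leg feature block,
#' outcome residuals, TM outcomes, ultrasound repeat jitter.
#'
#' @param config a [sim_config()].
#' @return list with `ultrasound`, `clinical`, `features` (the three raw
#'   tables), and `truth` (per-patient random intercepts, per-leg true
#'   %active and noiseless outcomes, and the planted betas).
#' @export
#' @examples
#' set.seed(7)
#' cohort <- simulate_cohort(sim_config(n_patients = 8))
#' head(cohort$clinical)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_patients < 2) stop("need n_patients >= 2", call. = FALSE)
  np <- config$n_patients
  pid <- sprintf("P%03d", seq_len(np))

  # --- patient-level clinical block ---
  age <- round(rnorm_trunc_pos(np, 59.2, 15.9))
  sex <- stats::rbinom(np, 1, 0.585) # 1 = male
  msofa <- pmax(round(stats::rnorm(np, 4.5, 2.1)), 0)
  weight <- rnorm_trunc_pos(np, 75, 14)
  cal_adeq <- pmin(pmax(stats::rnorm(np, 62.6, 18.4), 5), 140)
  pro_adeq <- pmin(pmax(stats::rnorm(np, 57.9, 21.6), 5), 140)
  # 10 days of prescription: hypocaloric (70%) days 1-3, isocaloric after
  deficits <- t(vapply(seq_len(np), function(i) {
    presc_cal <- 25 * weight[i] * c(rep(0.7, 3), rep(1, 7))
    presc_pro <- 1.3 * weight[i] * c(rep(0.7, 3), rep(1, 7))
    cal <- cumulative_deficit(presc_cal, presc_cal * cal_adeq[i] / 100)
    pro <- cumulative_deficit(presc_pro, presc_pro * pro_adeq[i] / 100)
    c(cal$deficit, pro$deficit)
  }, numeric(2)))
  # full SOFA = mSOFA plus a neurology (GCS) component that tracks age;
  # being a composite of two sources, it draws the higher VIF of the pair
  sofa <- msofa + pmax(round(2 + 1.2 * scale(age)[, 1] + stats::rnorm(np, 0, 0.6)), 0)

  baseline_rfm <- rnorm_trunc_pos(np, config$baseline_rfm_mean_mm, config$baseline_rfm_sd_mm)
  baseline_tm <- rnorm_trunc_pos(np, config$baseline_tm_mean_mm, config$baseline_tm_sd_mm)
  u <- stats::rnorm(np, 0, config$random_intercept_sd)

  clinical <- data.frame(
    patient_id = pid, age = age, sex = sex, msofa = msofa, sofa = sofa,
    calorie_deficit = deficits[, 1], protein_deficit = deficits[, 2]
  )

  # --- leg availability: reproduce ~91 usable legs from 53 patients ---
  legs <- do.call(rbind, lapply(seq_len(np), function(i) {
    sides <- c("L", "R")
    if (config$legs_per_patient >= 2 &&
      stats::runif(1) < config$leg_missing_prob) {
      sides <- sample(sides, 1)
    }
    if (config$legs_per_patient == 1) sides <- "L"
    data.frame(patient_id = pid[i], side = sides)
  }))

  nl <- nrow(legs)
  pa_par <- lnorm_params(config$pct_active_mean, config$pct_active_sd)
  pct_active <- stats::rlnorm(nl, pa_par$meanlog, pa_par$sdlog)
  ab_dur_logmean <- stats::rnorm(nl, config$bout_duration_logmean, 0.4)
  ab_dur_logsd <- rnorm_trunc_pos(nl, config$bout_duration_logsd, 0.1)
  ab_int_logmean <- stats::rnorm(nl, config$bout_intensity_logmean, 0.15)
  ab_int_logsd <- rnorm_trunc_pos(nl, config$bout_intensity_logsd, 0.08)
  overall_int <- stats::rlnorm(nl, log(0.03), 0.5)
  # bouts/hour rises with active time and falls with longer bouts; a
  # composite of two sources, like the full SOFA score above
  typ_dur <- exp(config$bout_duration_logmean + config$bout_duration_logsd^2 / 2)
  ab_per_hour <- pmax(
    0.8 + pct_active * 36 / typ_dur -
      3 * (ab_dur_logmean - config$bout_duration_logmean) +
      stats::rnorm(nl, 0, 0.3),
    0
  )
  if (config$confounded) {
    # robustness switch: let overall intensity track %active
    overall_int <- overall_int * (1 + pct_active / 10)
  }

  # limb grouping for the secondary GEE contrast
  iu <- match(legs$patient_id, pid)
  umnl <- stats::rbinom(nl, 1, 0.3)
  limb_group <- ifelse(pct_active > stats::quantile(pct_active, 2 / 3), "active",
    ifelse(umnl == 1, "immobile_umnl", "immobile_no_umnl")
  )

  features <- data.frame(
    patient_id = legs$patient_id, side = legs$side,
    pct_active = pct_active,
    overall_intensity_g = overall_int,
    ab_per_hour = ab_per_hour,
    ab_intensity_logmean = ab_int_logmean,
    ab_intensity_logsd = ab_int_logsd,
    ab_duration_logmean = ab_dur_logmean,
    ab_duration_logsd = ab_dur_logsd,
    limb_group = limb_group
  )

  # --- outcomes ---
  z_rfm <- (baseline_rfm[iu] - config$baseline_rfm_mean_mm) / config$baseline_rfm_sd_mm
  z_act <- (pct_active - config$pct_active_mean) / config$pct_active_sd
  signal10 <- config$true_beta_baseline_rfm * z_rfm +
    config$true_beta_pct_active * z_act + u[iu]
  days <- as.numeric(names(config$day_fractions))
  frac <- as.numeric(config$day_fractions)

  obs <- do.call(rbind, lapply(seq_along(days), function(d) {
    data.frame(
      patient_id = legs$patient_id, side = legs$side, day = days[d],
      noiseless = frac[d] * config$atrophy_intercept_pct + signal10
    )
  }))
  obs$outcome <- obs$noiseless + stats::rnorm(nrow(obs), 0, config$residual_sd)

  # TM day-10 change, independent of leg movement by construction
  tm_change <- stats::rnorm(nl, config$tm_atrophy_mean_pct, config$tm_atrophy_sd_pct)

  # --- ultrasound repeats (RFM all days, TM day 0 and 10) ---
  mk_rep <- function(thick) {
    thick <- pmax(thick, 0.5)
    reps <- matrix(
      pmax(thick + stats::rnorm(3 * length(thick), 0, config$repeat_sd_mm), 0.1),
      ncol = 3
    )
    # keep the mean of the three repeats exactly on the drawn thickness
    reps - rowMeans(reps) + thick
  }
  rfm0 <- data.frame(
    patient_id = legs$patient_id, side = legs$side, muscle = "RFM", day = 0,
    thick = baseline_rfm[iu]
  )
  rfm_f <- data.frame(
    patient_id = obs$patient_id, side = obs$side, muscle = "RFM", day = obs$day,
    thick = baseline_rfm[match(obs$patient_id, pid)] * (1 + obs$outcome / 100)
  )
  tm0 <- data.frame(
    patient_id = legs$patient_id, side = legs$side, muscle = "TM", day = 0,
    thick = baseline_tm[iu]
  )
  tm10 <- data.frame(
    patient_id = legs$patient_id, side = legs$side, muscle = "TM", day = 10,
    thick = baseline_tm[iu] * (1 + tm_change / 100)
  )
  us <- rbind(rfm0, rfm_f, tm0, tm10)
  reps <- mk_rep(us$thick)
  ultrasound <- data.frame(
    patient_id = us$patient_id, side = us$side, muscle = us$muscle,
    day = us$day, rep1 = reps[, 1], rep2 = reps[, 2], rep3 = reps[, 3]
  )

  truth <- list(
    random_intercepts = stats::setNames(u, pid),
    beta = c(
      baseline_rfm = config$true_beta_baseline_rfm,
      pct_active = config$true_beta_pct_active
    ),
    intercept = config$atrophy_intercept_pct,
    legs = data.frame(
      patient_id = legs$patient_id, side = legs$side,
      pct_active = pct_active, baseline_rfm_mm = baseline_rfm[iu],
      day10_noiseless = config$atrophy_intercept_pct + signal10,
      tm_day10_change = tm_change
    ),
    observations = obs
  )
  list(
    ultrasound = ultrasound, clinical = clinical,
    features = features, truth = truth
  )
}

#' Simulate a ready-to-model analysis table
#'
#' Convenience wrapper: [simulate_cohort()] followed by
#' [build_analysis_table()].
#'
#' @param config a [sim_config()].
#' @param days follow-up days to keep (default day 10 only, where the
#'   planted effects are defined on their own scale).
#' @return the analysis table, with the cohort's ground truth attached as
#'   attribute `"truth"`.
#' @export
simulate_analysis_table <- function(config, days = 10) {
  cohort <- simulate_cohort(config)
  tab <- build_analysis_table(
    cohort$ultrasound, cohort$clinical, cohort$features,
    days = days
  )
  attr(tab, "truth") <- cohort$truth
  tab
}
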