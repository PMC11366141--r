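#' Simulation configuration for the synthetic neuro-ICU cohort
#'
#' Bundles every parameter of the synthetic-data generator: sensor
#' characteristics, activity-bout laws, exclusion-episode rate, and the
#' linear outcome model that links baseline rectus femoris (RFM) thickness
#' and the proportion of active movement to day-10 muscle atrophy.
#'
#' Defaults emulate the study cohort the generator is modelled on:
#' 53 patients with ~91 leg datasets, baseline RFM thickness
#' 10.3 (SD 2.6) mm, %active 0.84 (SD 1.08), mean day-10 RFM atrophy
#' -19.5% with marginal SD ~12, standardized effects -5.1 percentage
#' points per SD of baseline RFM and +1.6 per SD of %active, and a
#' +-16 g, 12.5 Hz tri-axial accelerometer. The `"healthy"` preset
#' raises the bout rate so that %active lands above 10%, mimicking
#' ambulatory controls (%active ~13).
#'
#' @param n_patients number of patients in the cohort.
#' @param legs_per_patient legs instrumented per patient (2).
#' @param leg_missing_prob probability that one of a patient's two legs has
#'   no usable recording (default 15/53, reproducing ~91 leg datasets from
#'   53 patients).
#' @param recording_hours length of each accelerometer recording.
#' @param sample_rate_hz sensor sampling rate in Hz; must exceed 0.4 Hz so
#'   the 0.2 Hz high-pass cutoff stays below Nyquist.
#' @param bout_rate_per_hour mean number of planted activity bouts per hour.
#' @param bout_duration_logmean,bout_duration_logsd log-normal law of bout
#'   durations (natural-log seconds).
#' @param bout_intensity_logmean,bout_intensity_logsd log-normal law of bout
#'   intensities (natural-log g).
#' @param detectable_bouts if `TRUE`, bout intensities are redrawn until
#'   they reach at least twice the detection threshold (0.135 g), so every
#'   planted bout is recoverable downstream.
#' @param noise_sd_g standard deviation of the zero-mean sensor noise (g).
#' @param gravity_orientation unit 3-vector of the static gravity component.
#' @param exclusion_episodes_per_day mean number of passive-movement
#'   episodes (physiotherapy, transport, repositioning) per 24 h.
#' @param true_beta_baseline_rfm,true_beta_pct_active standardized fixed
#'   effects (percentage points of day-10 atrophy per SD of the predictor).
#' @param random_intercept_sd,residual_sd SDs (percentage points) of the
#'   patient random intercept and of the per-observation residual.
#' @param baseline_rfm_mean_mm,baseline_rfm_sd_mm baseline RFM thickness law
#'   (truncated positive normal).
#' @param baseline_tm_mean_mm,baseline_tm_sd_mm baseline temporalis (TM)
#'   thickness law.
#' @param atrophy_intercept_pct mean day-10 RFM change (%) at average
#'   predictor values.
#' @param tm_atrophy_mean_pct,tm_atrophy_sd_pct day-10 TM change law; TM is
#'   generated independent of leg movement.
#' @param day_fractions named fractions applied to the mean atrophy
#'   trajectory at days 3 and 7 relative to day 10.
#' @param pct_active_mean,pct_active_sd target moments of the %active law
#'   (log-normal, moment-matched) used when leg features are drawn directly
#'   rather than extracted from simulated recordings.
#' @param repeat_sd_mm SD of the jitter between the three repeated
#'   ultrasound measurements.
#' @param confounded if `TRUE`, nuisance predictors are generated with mild
#'   dependence on the outcome's linear predictor (robustness switch);
#'   default independent.
#' @param preset `"nicu"` (default) or `"healthy"`.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 10, recording_hours = 1)
#' cfg$sample_rate_hz
sim_config <- function(n_patients = 53,
                       legs_per_patient = 2,
                       leg_missing_prob = 15 / 53,
                       recording_hours = 24,
                       sample_rate_hz = 12.5,
                       bout_rate_per_hour = 1.7,
                       bout_duration_logmean = log(15),
                       bout_duration_logsd = 0.6,
                       bout_intensity_logmean = log(0.25),
                       bout_intensity_logsd = 0.4,
                       detectable_bouts = FALSE,
                       noise_sd_g = 0.02,
                       gravity_orientation = c(0, 0, 1),
                       exclusion_episodes_per_day = 8,
                       true_beta_baseline_rfm = -5.1,
                       true_beta_pct_active = 1.6,
                       random_intercept_sd = 7,
                       residual_sd = 8,
                       baseline_rfm_mean_mm = 10.3,
                       baseline_rfm_sd_mm = 2.6,
                       baseline_tm_mean_mm = 6.9,
                       baseline_tm_sd_mm = 1.5,
                       atrophy_intercept_pct = -19.5,
                       tm_atrophy_mean_pct = -15.3,
                       tm_atrophy_sd_pct = 11.1,
                       day_fractions = c("3" = 0.4, "7" = 0.8, "10" = 1),
                       pct_active_mean = 0.84,
                       pct_active_sd = 1.08,
                       repeat_sd_mm = 0.1,
                       confounded = FALSE,
                       preset = c("nicu", "healthy")) {
  preset <- match.arg(preset)
  if (preset == "healthy") {
    # ambulatory controls: frequent, longer bouts -> %active > 10
    if (missing(bout_rate_per_hour)) bout_rate_per_hour <- 20
    if (missing(bout_duration_logmean)) bout_duration_logmean <- log(20)
    if (missing(pct_active_mean)) pct_active_mean <- 13.3
    if (missing(pct_active_sd)) pct_active_sd <- 0.8
  }
  cfg <- list(
    n_patients = n_patients, legs_per_patient = legs_per_patient,
    leg_missing_prob = leg_missing_prob,
    recording_hours = recording_hours, sample_rate_hz = sample_rate_hz,
    bout_rate_per_hour = bout_rate_per_hour,
    bout_duration_logmean = bout_duration_logmean,
    bout_duration_logsd = bout_duration_logsd,
    bout_intensity_logmean = bout_intensity_logmean,
    bout_intensity_logsd = bout_intensity_logsd,
    detectable_bouts = detectable_bouts,
    noise_sd_g = noise_sd_g,
    gravity_orientation = gravity_orientation,
    exclusion_episodes_per_day = exclusion_episodes_per_day,
    true_beta_baseline_rfm = true_beta_baseline_rfm,
    true_beta_pct_active = true_beta_pct_active,
    random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd,
    baseline_rfm_mean_mm = baseline_rfm_mean_mm,
    baseline_rfm_sd_mm = baseline_rfm_sd_mm,
    baseline_tm_mean_mm = baseline_tm_mean_mm,
    baseline_tm_sd_mm = baseline_tm_sd_mm,
    atrophy_intercept_pct = atrophy_intercept_pct,
    tm_atrophy_mean_pct = tm_atrophy_mean_pct,
    tm_atrophy_sd_pct = tm_atrophy_sd_pct,
    day_fractions = day_fractions,
    pct_active_mean = pct_active_mean, pct_active_sd = pct_active_sd,
    repeat_sd_mm = repeat_sd_mm,
    confounded = confounded,
    preset = preset
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c(
    "recording_hours", "sample_rate_hz", "bout_duration_logsd",
    "bout_intensity_logsd", "random_intercept_sd", "residual_sd",
    "baseline_rfm_mean_mm", "baseline_rfm_sd_mm",
    "baseline_tm_mean_mm", "baseline_tm_sd_mm",
    "tm_atrophy_sd_pct", "pct_active_mean", "pct_active_sd"
  )
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("sim_config: '", nm, "' must be a single positive number",
        call. = FALSE
      )
    }
  }
  nonneg <- c(
    "bout_rate_per_hour", "noise_sd_g", "exclusion_episodes_per_day",
    "leg_missing_prob", "repeat_sd_mm"
  )
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("sim_config: '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (cfg$sample_rate_hz <= 0.4) {
    stop("sim_config: sample_rate_hz must exceed 0.4 Hz (filter cutoff ",
      "must lie below Nyquist)",
      call. = FALSE
    )
  }
  g <- cfg$gravity_orientation
  if (length(g) != 3 || abs(sqrt(sum(g^2)) - 1) > 1e-8) {
    stop("sim_config: gravity_orientation must be a unit 3-vector",
      call. = FALSE
    )
  }
  if (cfg$n_patients < 1 || cfg$legs_per_patient < 1) {
    stop("sim_config: need at least one patient and one leg", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> preset:", x$preset, "\n")
  cat(sprintf(
    "  %d patients, %.1f h recordings at %.1f Hz\n",
    x$n_patients, x$recording_hours, x$sample_rate_hz
  ))
  cat(sprintf(
    "  bouts: %.2f/h, duration ~ logN(%.2f, %.2f) s, intensity ~ logN(%.2f, %.2f) g\n",
    x$bout_rate_per_hour, x$bout_duration_logmean, x$bout_duration_logsd,
    x$bout_intensity_logmean, x$bout_intensity_logsd
  ))
  cat(sprintf(
    "  outcome: intercept %.1f%%, beta(baseline RFM) %.1f, beta(%%active) %.1f\n",
    x$atrophy_intercept_pct, x$true_beta_baseline_rfm, x$true_beta_pct_active
  ))
  invisible(x)
}
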