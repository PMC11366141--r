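#' Simulate exclusion episodes for a recording span
#'
#' Draws non-overlapping `[start, end)` episodes of passive movement
#' (physiotherapy, transport, repositioning) within `[0, duration_s)`.
#' The episode count is Poisson with mean
#' `exclusion_episodes_per_day * duration_s / 86400`; durations are uniform
#' between 10 and 40 minutes (clipped to the recording span), echoing
#' typical physiotherapy and repositioning session lengths.
#'
#' @param config a [sim_config()].
#' @param duration_s recording span in seconds.
#' @return data frame with columns `start_s`, `end_s`, `reason`
#'   (pairwise-disjoint, sorted).
#' @export
simulate_exclusions <- function(config, duration_s) {
  validate_sim_config(config)
  stopifnot(duration_s > 0)
  n <- stats::rpois(1, config$exclusion_episodes_per_day * duration_s / 86400)
  reasons <- c("physiotherapy", "transport", "repositioning")
  out <- data.frame(
    start_s = numeric(0), end_s = numeric(0),
    reason = character(0)
  )
  if (n == 0) {
    return(out)
  }
  starts <- sort(stats::runif(n, 0, duration_s))
  durs <- stats::runif(n, 10 * 60, 40 * 60)
  reason <- sample(reasons, n, replace = TRUE)
  ends <- pmin(starts + durs, duration_s)
  # enforce pairwise disjointness: truncate each episode at the next start
  if (n > 1) ends[-n] <- pmin(ends[-n], starts[-1])
  keep <- ends > starts
  data.frame(
    start_s = starts[keep], end_s = ends[keep],
    reason = reason[keep], stringsAsFactors = FALSE
  )
}

# sample bout start times with a minimum separation, all clear of the
# excluded intervals; returns at most n_bouts starts
place_bouts <- function(n_bouts, durations, duration_s, exclusions,
                        min_gap_s = 10, max_tries = 200) {
  starts <- numeric(0)
  kept_dur <- numeric(0)
  occupied_s <- numeric(0)
  occupied_e <- numeric(0)
  if (nrow(exclusions)) {
    occupied_s <- exclusions$start_s - min_gap_s
    occupied_e <- exclusions$end_s + min_gap_s
  }
  for (k in seq_len(n_bouts)) {
    d <- durations[k]
    if (d + 2 * min_gap_s >= duration_s) next
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- stats::runif(1, min_gap_s, duration_s - d - min_gap_s)
      e <- s + d
      clash <- any(s < occupied_e + min_gap_s & e > occupied_s - min_gap_s)
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (ok) {
      starts <- c(starts, s)
      kept_dur <- c(kept_dur, d)
      occupied_s <- c(occupied_s, s)
      occupied_e <- c(occupied_e, e)
    }
  }
  ord <- order(starts)
  list(start_s = starts[ord], duration_s = kept_dur[ord])
}

#' Simulate one leg's accelerometer recording with planted activity bouts
#'
#' The raw series is the sum of a static 1 g gravity component along
#' `gravity_orientation`, zero-mean Gaussian sensor noise, and planted
#' bout segments: a 2 Hz sinusoid on the axis most orthogonal to gravity,
#' with its amplitude scaled so that the rectified three-axis mean of the
#' noise-free bout samples equals the planted intensity (which makes the
#' planted intensity analytically checkable after filtering). Bout
#' log-durations and log-intensities follow the configured log-normal
#' laws; bouts are non-overlapping, separated by at least 10 s, and are
#' placed clear of the exclusion episodes. Values are clipped to +-16 g.
#'
#' Draw order (one seeded stream): exclusion episodes, bout count, bout
#' durations, bout intensities, bout placement, sensor noise.
#'
#' @param config a [sim_config()].
#' @param leg_id,patient_id identifiers.
#' @param exclusions optional pre-drawn exclusion log (data frame with
#'   `start_s`, `end_s`); drawn via [simulate_exclusions()] when `NULL`.
#' @return a list with elements `recording` ([accel_recording()]),
#'   `exclusions` (episode data frame) and `truth` (planted bout table,
#'   true %active of non-excluded time, and per-bout amplitudes).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 1, recording_hours = 0.5, noise_sd_g = 0.01)
#' set.seed(1)
#' sim <- simulate_recording(cfg, leg_id = "P01_L")
#' sim$truth$pct_active
simulate_recording <- function(config, leg_id = "L1", patient_id = "P1",
                               exclusions = NULL) {
  validate_sim_config(config)
  if (config$recording_hours <= 0) {
    stop("recording_hours must be positive", call. = FALSE)
  }
  fs <- config$sample_rate_hz
  duration_s <- config$recording_hours * 3600
  n <- floor(duration_s * fs) + 1
  t <- (seq_len(n) - 1) / fs

  if (is.null(exclusions)) {
    exclusions <- simulate_exclusions(config, duration_s)
  }

  n_bouts <- stats::rpois(1, config$bout_rate_per_hour * config$recording_hours)
  durations <- stats::rlnorm(
    max(n_bouts, 0), config$bout_duration_logmean, config$bout_duration_logsd
  )
  intensities <- stats::rlnorm(
    max(n_bouts, 0), config$bout_intensity_logmean, config$bout_intensity_logsd
  )
  if (config$detectable_bouts && n_bouts > 0) {
    # truncated law: redraw until the bout clears twice the 0.135 g threshold
    low <- intensities < 2 * 0.135
    while (any(low)) {
      intensities[low] <- stats::rlnorm(
        sum(low), config$bout_intensity_logmean, config$bout_intensity_logsd
      )
      low <- intensities < 2 * 0.135
    }
  }

  placed <- place_bouts(n_bouts, durations, duration_s, exclusions)
  k <- length(placed$start_s)
  intensities <- intensities[seq_len(k)]

  g <- config$gravity_orientation
  acc <- matrix(stats::rnorm(3 * n, 0, config$noise_sd_g), ncol = 3)
  acc <- sweep(acc, 2, g, "+")

  # oscillation axis: the one carrying the least gravity
  axis <- which.min(abs(g))
  amp <- numeric(k)
  for (j in seq_len(k)) {
    idx <- which(t >= placed$start_s[j] & t < placed$start_s[j] + placed$duration_s[j])
    if (!length(idx)) next
    wave <- sin(2 * pi * 2 * (t[idx] - placed$start_s[j]))
    m <- mean(abs(wave))
    if (m < 1e-9) next
    # scale so the rectified three-axis mean of the noise-free bout samples
    # (gravity removed) equals the planted intensity
    amp[j] <- intensities[j] / m # |x|+|y|+|z| has only this axis oscillating
    acc[idx, axis] <- acc[idx, axis] + amp[j] * wave
  }
  acc <- pmin(pmax(acc, -16), 16)

  rec <- accel_recording(t, acc, fs, leg_id = leg_id, patient_id = patient_id)

  excl_s <- total_excluded_seconds(exclusions, duration_s)
  active_s <- sum(placed$duration_s[seq_len(k)])
  truth <- list(
    bouts = data.frame(
      start_s = placed$start_s,
      duration_s = placed$duration_s,
      intensity_g = intensities,
      amplitude_g = amp
    ),
    pct_active = if (duration_s - excl_s > 0) {
      100 * active_s / (duration_s - excl_s)
    } else {
      NA_real_
    },
    n_bouts = k
  )
  list(recording = rec, exclusions = exclusions, truth = truth)
}

# total length of the union of [start, end) intervals clipped to [0, span)
total_excluded_seconds <- function(episodes, span_s) {
  if (!nrow(episodes)) {
    return(0)
  }
  m <- merge_intervals(
    pmax(episodes$start_s, 0),
    pmin(episodes$end_s, span_s)
  )
  sum(pmax(m$end - m$start, 0))
}

# merge overlapping [start, end) intervals
merge_intervals <- function(start, end) {
  keep <- end > start
  start <- start[keep]
  end <- end[keep]
  if (!length(start)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
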