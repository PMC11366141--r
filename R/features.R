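#' Down-sample a recording to 10 Hz by linear interpolation
#'
#' Places a uniform 10 Hz grid over the span of the input and linearly
#' interpolates each axis. A recording already on a 10 Hz grid is
#' returned unchanged. Excluded-sample flags are carried over by
#' interval membership (a resampled point is excluded if its time falls
#' inside an excluded stretch of the original grid).
#'
#' @param rec an [accel_recording()] with `sample_rate_hz >= 10`.
#' @param target_hz output rate (default 10).
#' @return an [accel_recording()] on the target grid.
#' @export
resample_to_10hz <- function(rec, target_hz = 10) {
  stopifnot(inherits(rec, "accel_recording"))
  if (rec$sample_rate_hz < target_hz) {
    stop("input sampling rate (", rec$sample_rate_hz,
      " Hz) is below the target rate",
      call. = FALSE
    )
  }
  gap <- first_irregular_gap(rec$time_s)
  if (gap > 0) {
    stop(sprintf(
      "non-uniform sample grid: first irregular gap after sample %d (t = %.6f s)",
      gap, rec$time_s[gap]
    ), call. = FALSE)
  }
  if (abs(rec$sample_rate_hz - target_hz) < 1e-9) {
    return(rec)
  }
  t_new <- seq(rec$time_s[1], rec$time_s[length(rec$time_s)], by = 1 / target_hz)
  acc_new <- vapply(
    1:3,
    function(j) stats::approx(rec$time_s, rec$acc[, j], xout = t_new)$y,
    numeric(length(t_new))
  )
  excl_new <- if (any(rec$excluded)) {
    stats::approx(rec$time_s, as.numeric(rec$excluded),
      xout = t_new, method = "constant", f = 0
    )$y > 0.5
  } else {
    rep(FALSE, length(t_new))
  }
  accel_recording(t_new, acc_new, target_hz,
    leg_id = rec$leg_id, patient_id = rec$patient_id, excluded = excl_new
  )
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes the static gravity component and slow postural drift with a
#' 4th-order Butterworth high-pass (default cutoff 0.2 Hz) applied
#' forward-backward (zero phase), so bout edges are not shifted in time.
#' The forward-backward pass squares the magnitude response, doubling the
#' stopband attenuation.
#'
#' @param rec an [accel_recording()].
#' @param cutoff_hz high-pass cutoff (Hz), must be below Nyquist.
#' @param order filter order (4).
#' @return the filtered [accel_recording()].
#' @export
highpass_filter <- function(rec, cutoff_hz = 0.2, order = 4) {
  stopifnot(inherits(rec, "accel_recording"))
  fs <- rec$sample_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  settle_s <- 3 / cutoff_hz # ~15 s at 0.2 Hz
  if (diff(range(rec$time_s)) < 3 * settle_s) {
    stop(sprintf(
      "recording too short for the %.2g Hz high-pass: need at least %.0f s",
      cutoff_hz, 3 * settle_s
    ), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  acc_f <- apply(rec$acc, 2, function(v) signal::filtfilt(bf, v))
  acc_f <- pmin(pmax(acc_f, -16), 16)
  accel_recording(rec$time_s, acc_f, fs,
    leg_id = rec$leg_id, patient_id = rec$patient_id, excluded = rec$excluded
  )
}

#' Flag samples inside exclusion episodes
#'
#' Marks every sample whose time falls in any `[start_s, end_s)` episode
#' as excluded; overlapping episodes are merged and episodes are clipped
#' to the recording span. Excluded samples contribute to no window
#' statistic downstream.
#'
#' @param rec an [accel_recording()].
#' @param episodes data frame with columns `start_s`, `end_s` (and
#'   optionally `reason`).
#' @return the recording with its `excluded` mask updated.
#' @export
mask_exclusions <- function(rec, episodes) {
  stopifnot(inherits(rec, "accel_recording"))
  if (is.null(episodes) || nrow(episodes) == 0) {
    return(rec)
  }
  if (any(episodes$start_s >= episodes$end_s)) {
    stop("exclusion episodes must have start_s < end_s", call. = FALSE)
  }
  m <- merge_intervals(
    pmax(episodes$start_s, rec$time_s[1]),
    pmin(episodes$end_s, rec$time_s[length(rec$time_s)] + 1 / rec$sample_rate_hz)
  )
  excl <- rec$excluded
  for (i in seq_len(nrow(m))) {
    excl <- excl | (rec$time_s >= m$start[i] & rec$time_s < m$end[i])
  }
  rec$excluded <- excl
  rec
}

#' Signal magnitude area per non-overlapping 5 s window
#'
#' Segments the (filtered, 10 Hz) recording into contiguous,
#' non-overlapping windows of `window_s` seconds and computes, for each,
#' the signal magnitude area (SMA): the mean over the window's samples of
#' `|x| + |y| + |z|`, in g. This is the windowed integral of the
#' rectified three-axis sum divided by the window length, so the value is
#' scale-free with respect to the window length. A window containing any
#' excluded sample is wholly marked excluded; a trailing partial window
#' is dropped.
#'
#' @param rec an [accel_recording()] (high-pass filtered, uniform grid).
#' @param window_s window length in seconds (default 5); `window_s *
#'   sample_rate_hz` must be a whole number of samples.
#' @return an object of class `window_series`: data frame with columns
#'   `window_start_s`, `sma_g`, `excluded`, plus attributes `window_s`
#'   and `sample_rate_hz`.
#' @export
compute_sma <- function(rec, window_s = 5) {
  stopifnot(inherits(rec, "accel_recording"))
  spw <- window_s * rec$sample_rate_hz
  if (abs(spw - round(spw)) > 1e-9) {
    stop("window_s must correspond to a whole number of samples", call. = FALSE)
  }
  spw <- as.integer(round(spw))
  n_win <- length(rec$time_s) %/% spw
  if (n_win < 1) stop("recording shorter than one window", call. = FALSE)
  n_use <- n_win * spw
  rect <- rowSums(abs(rec$acc[seq_len(n_use), , drop = FALSE]))
  grp <- rep(seq_len(n_win), each = spw)
  sma <- as.numeric(tapply(rect, grp, mean))
  excl <- as.logical(tapply(rec$excluded[seq_len(n_use)], grp, any))
  ws <- data.frame(
    window_start_s = rec$time_s[seq(1, n_use, by = spw)],
    sma_g = sma, excluded = excl
  )
  attr(ws, "window_s") <- window_s
  attr(ws, "sample_rate_hz") <- rec$sample_rate_hz
  class(ws) <- c("window_series", "data.frame")
  ws
}

#' Detect activity bouts in a window series
#'
#' An activity bout is a maximal run of consecutive non-excluded windows
#' with SMA at or above the threshold (the threshold itself counts as
#' active). Excluded windows break runs; a single sub-threshold window
#' ends a bout (no gap tolerance). Bout duration is the window length
#' times the run length; bout intensity is the mean SMA over the run.
#'
#' @param ws a `window_series` from [compute_sma()].
#' @param threshold_g activity threshold in g (default 0.135).
#' @return data frame with columns `start_s`, `duration_s`,
#'   `intensity_g`, `n_windows` (possibly zero rows).
#' @export
detect_bouts <- function(ws, threshold_g = 0.135) {
  stopifnot(inherits(ws, "window_series"))
  window_s <- attr(ws, "window_s")
  active <- !ws$excluded & ws$sma_g >= threshold_g
  empty <- data.frame(
    start_s = numeric(0), duration_s = numeric(0),
    intensity_g = numeric(0), n_windows = integer(0)
  )
  if (!any(active)) {
    return(empty)
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start_s = ws$window_start_s[starts[keep]],
    duration_s = r$lengths[keep] * window_s,
    intensity_g = vapply(
      keep,
      function(k) mean(ws$sma_g[starts[k]:ends[k]]), numeric(1)
    ),
    n_windows = r$lengths[keep]
  )
}

#' Closed-form maximum-likelihood fit of a log-normal distribution
#'
#' For strictly positive values, the ML estimates are the mean of the
#' natural logs and the population (divide-by-n) standard deviation of
#' the natural logs.
#'
#' @param values positive numeric vector.
#' @return list with `logmean` and `logsd`; both `NA` for an empty input.
#' @export
#' @examples
#' lognormal_mle(c(1, exp(2))) # logmean 1, logsd 1
lognormal_mle <- function(values) {
  if (length(values) == 0) {
    return(list(logmean = NA_real_, logsd = NA_real_))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("lognormal_mle: all values must be positive and finite", call. = FALSE)
  }
  lx <- log(values)
  m <- mean(lx)
  list(logmean = m, logsd = sqrt(mean((lx - m)^2)))
}

#' Movement feature set for one recording
#'
#' Aggregates a window series and its detected bouts into the seven
#' movement biomarkers: `%active` (share of non-excluded windows that are
#' active), overall intensity (mean SMA over all non-excluded windows),
#' bouts per non-excluded hour, and the log-normal ML location/scale of
#' bout intensities and durations. With zero bouts the four log features
#' are `NA`. By construction, the summed bout durations equal
#' `pct_active/100` times the analyzed (non-excluded) duration exactly.
#'
#' @param ws a `window_series` from [compute_sma()].
#' @param bouts bout table from [detect_bouts()]; recomputed when `NULL`.
#' @param threshold_g activity threshold used when `bouts` is `NULL`.
#' @return an object of class `movement_features`: a one-row data frame
#'   with columns `pct_active`, `overall_intensity_g`, `ab_per_hour`,
#'   `ab_intensity_logmean`, `ab_intensity_logsd`,
#'   `ab_duration_logmean`, `ab_duration_logsd`, `n_bouts`,
#'   `analyzed_hours`.
#' @export
extract_features <- function(ws, bouts = NULL, threshold_g = 0.135) {
  stopifnot(inherits(ws, "window_series"))
  window_s <- attr(ws, "window_s")
  keep <- !ws$excluded
  if (!any(keep)) {
    stop("no non-excluded windows: nothing to analyze", call. = FALSE)
  }
  if (is.null(bouts)) bouts <- detect_bouts(ws, threshold_g)
  n_nonexcl <- sum(keep)
  analyzed_hours <- n_nonexcl * window_s / 3600
  n_bouts <- nrow(bouts)
  active_windows <- if (n_bouts) sum(bouts$n_windows) else 0L
  fi <- lognormal_mle(bouts$intensity_g)
  fd <- lognormal_mle(bouts$duration_s)
  out <- data.frame(
    pct_active = 100 * active_windows / n_nonexcl,
    overall_intensity_g = mean(ws$sma_g[keep]),
    ab_per_hour = n_bouts / analyzed_hours,
    ab_intensity_logmean = fi$logmean,
    ab_intensity_logsd = fi$logsd,
    ab_duration_logmean = fd$logmean,
    ab_duration_logsd = fd$logsd,
    n_bouts = n_bouts,
    analyzed_hours = analyzed_hours
  )
  class(out) <- c("movement_features", "data.frame")
  out
}

#' Raw recording to movement features in one call
#'
#' Chains the processing pipeline: down-sample to 10 Hz, 4th-order
#' zero-phase Butterworth high-pass at 0.2 Hz, exclusion masking,
#' 5 s window SMA, bout detection at 0.135 g, feature aggregation.
#'
#' @param rec an [accel_recording()].
#' @param episodes optional exclusion-episode data frame.
#' @param threshold_g,window_s,cutoff_hz,order,target_hz pipeline
#'   parameters (defaults 0.135 g, 5 s, 0.2 Hz, 4, 10 Hz).
#' @return a `movement_features` row (see [extract_features()]).
#' @export
movement_features <- function(rec, episodes = NULL, threshold_g = 0.135,
                              window_s = 5, cutoff_hz = 0.2, order = 4,
                              target_hz = 10) {
  rec <- resample_to_10hz(rec, target_hz)
  rec <- highpass_filter(rec, cutoff_hz, order)
  if (!is.null(episodes)) rec <- mask_exclusions(rec, episodes)
  ws <- compute_sma(rec, window_s)
  extract_features(ws, threshold_g = threshold_g)
}
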