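#' Tri-axial accelerometer recording
#'
#' Container for one leg's acceleration time series on a uniform grid.
#' Values are in units of g and are expected to lie within the +-16 g
#' sensor range. An optional logical mask flags samples falling inside
#' exclusion episodes (passive movement such as physiotherapy,
#' intrahospital transport or repositioning); masked samples take part in
#' no downstream window statistic.
#'
#' @param time_s numeric vector of timestamps (seconds, uniform grid).
#' @param acc numeric matrix with columns `x`, `y`, `z` (g).
#' @param sample_rate_hz sampling rate (Hz).
#' @param leg_id,patient_id identifiers.
#' @param excluded optional logical vector flagging excluded samples.
#'
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(time_s, acc, sample_rate_hz,
                            leg_id = NA_character_, patient_id = NA_character_,
                            excluded = NULL) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acc must have three columns (x, y, z)", call. = FALSE)
  if (nrow(acc) != length(time_s)) {
    stop("time_s and acc must have the same number of samples", call. = FALSE)
  }
  if (any(abs(acc) > 16 + 1e-9)) {
    stop("acceleration values outside the +-16 g sensor range", call. = FALSE)
  }
  if (is.null(excluded)) excluded <- rep(FALSE, length(time_s))
  stopifnot(length(excluded) == length(time_s))
  colnames(acc) <- c("x", "y", "z")
  structure(
    list(
      time_s = as.numeric(time_s), acc = acc,
      sample_rate_hz = sample_rate_hz,
      leg_id = leg_id, patient_id = patient_id,
      excluded = as.logical(excluded)
    ),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %s / %s: %d samples at %.2f Hz (%.2f h), %.1f%% excluded\n",
    x$patient_id, x$leg_id, length(x$time_s), x$sample_rate_hz,
    diff(range(x$time_s)) / 3600, 100 * mean(x$excluded)
  ))
  invisible(x)
}

# first irregular gap index, or 0 if the grid is uniform within tol
first_irregular_gap <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) == 0) {
    return(0L)
  }
  bad <- which(abs(dt - dt[1]) > tol)
  if (length(bad) == 0) 0L else bad[1]
}

#' Write / read a recording as delimited text
#'
#' Recordings are stored with columns `t_s, ax_g, ay_g, az_g`; exclusion
#' logs with columns `start_s, end_s, reason`.
#'
#' @param rec an [accel_recording()].
#' @param path file path.
#' @return `read_recording()` returns an [accel_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(
    t_s = rec$time_s, ax_g = rec$acc[, 1],
    ay_g = rec$acc[, 2], az_g = rec$acc[, 3]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param sample_rate_hz sampling rate; inferred from the median timestamp
#'   spacing when `NULL`.
#' @param leg_id,patient_id identifiers attached to the recording.
#' @export
read_recording <- function(path, sample_rate_hz = NULL,
                           leg_id = NA_character_, patient_id = NA_character_) {
  df <- utils::read.csv(path)
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df))) {
    stop("recording file must have columns t_s, ax_g, ay_g, az_g", call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1 / stats::median(diff(df$t_s))
  }
  accel_recording(df$t_s, as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
    sample_rate_hz,
    leg_id = leg_id, patient_id = patient_id
  )
}

#' @rdname write_recording
#' @param episodes data frame with columns `start_s`, `end_s`, `reason`.
#' @export
write_exclusion_log <- function(episodes, path) {
  stopifnot(all(c("start_s", "end_s") %in% names(episodes)))
  if (is.null(episodes$reason)) episodes$reason <- "unspecified"
  utils::write.csv(episodes[, c("start_s", "end_s", "reason")], path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_exclusion_log <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop("exclusion log must have columns start_s, end_s", call. = FALSE)
  }
  if (any(df$start_s >= df$end_s)) {
    stop("exclusion episodes must have start_s < end_s", call. = FALSE)
  }
  df
}
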