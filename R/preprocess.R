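#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forwards and backwards
#' ([signal::filtfilt()]), so gait events keep their timing. The default
#' 12 Hz cutoff preserves gait-band content (< 10 Hz) while removing sensor
#' noise.
#'
#' @param x a `raw_recording` or a numeric vector.
#' @param cutoff_hz cutoff frequency, must satisfy `0 < cutoff < fs/2`.
#' @param order filter order.
#' @param fs sampling rate (numeric method only; taken from the recording
#'   otherwise).
#' @return object of the same type as `x`, filtered channel-wise.
#' @export
lowpass <- function(x, cutoff_hz = 12, order = 4, fs = NULL) {
  UseMethod("lowpass")
}

# zero-phase filtering with odd-reflection edge padding, so start/end
# transients decay inside the padding instead of distorting the signal
filtfilt_padded <- function(bf, x, fs, cutoff_hz) {
  n <- length(x)
  k <- min(n - 1L, ceiling(25 * fs / cutoff_hz))
  if (k < 2L) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1L] - x[(k + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - k)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(k + 1L):(k + n)]
}

#' @export
lowpass.numeric <- function(x, cutoff_hz = 12, order = 4, fs = NULL) {
  if (is.null(fs)) stop("fs is required for the numeric method")
  check_cutoff(cutoff_hz, fs)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_padded(bf, x, fs, cutoff_hz)
}

#' @export
lowpass.raw_recording <- function(x, cutoff_hz = 12, order = 4, fs = NULL) {
  fs <- fs %||% x$fs
  check_cutoff(cutoff_hz, fs)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  x$sensors <- lapply(x$sensors, function(s) {
    for (ch in c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"))
      s[[ch]] <- filtfilt_padded(bf, s[[ch]], fs, cutoff_hz)
    s
  })
  x
}

check_cutoff <- function(cutoff_hz, fs) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("configuration error: cutoff_hz must lie in (0, fs/2)")
  invisible(TRUE)
}

#' Estimate per-sensor orientation angles
#'
#' Tilt (sagittal and coronal, degrees relative to the gravity vertical;
#' backward positive, forward negative for the sagittal angle) comes from a
#' complementary filter blending the integrated gyroscope rate (weight
#' `blend`) with the accelerometer gravity tilt (weight `1 - blend`).
#' Heading (horizontal rotation, degrees, continuous - no +-180 wraps) is the
#' integral of the vertical-axis angular rate, optionally linearly detrended
#' between the rest states at the start and end of the recording.
#'
#' @param recording a (filtered) `raw_recording`.
#' @param blend complementary-filter weight given to the gyro path.
#' @param detrend_heading remove a linear heading drift anchored on the first
#'   and last `rest_s` seconds (assumed rest states).
#' @param rest_s rest-anchor duration in seconds.
#' @return an object of class `angle_series`: `fs`, `sensors` - named list of
#'   data frames with columns `t_s, sag_deg, cor_deg, heading_deg`.
#' @export
estimate_orientation <- function(recording, blend = 0.98,
                                 detrend_heading = TRUE, rest_s = 0.3) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  dt <- 1 / fs
  g <- 9.81
  rad2deg <- 180 / pi
  sensors <- lapply(names(recording$sensors), function(sn) {
    s <- recording$sensors[[sn]]
    nm <- sqrt(s$acc_x^2 + s$acc_y^2 + s$acc_z^2)
    if (stats::sd(nm) < 1e-12 && abs(mean(nm) - g) > 0.5 * g)
      warning("sensor ", sn, ": accelerometer norm far from gravity; ",
              "sensor likely detached")
    sag_acc <- atan2(s$acc_y, s$acc_z) * rad2deg
    cor_acc <- atan2(-s$acc_x, sqrt(s$acc_y^2 + s$acc_z^2)) * rad2deg
    sag <- complementary(sag_acc, s$gyr_x, dt, blend)
    cor <- complementary(cor_acc, s$gyr_y, dt, blend)
    heading <- cumsum(s$gyr_z) * dt
    if (detrend_heading) {
      k <- max(2L, round(rest_s * fs))
      n <- length(heading)
      h0 <- mean(heading[seq_len(k)])
      h1 <- mean(heading[(n - k + 1L):n])
      drift <- (h1 - h0) - 0 # start and end are rest states at equal heading
      heading <- heading - h0 - drift * (seq_len(n) - 1L) / (n - 1L)
    }
    data.frame(t_s = s$t_s, sag_deg = sag, cor_deg = cor, heading_deg = heading)
  })
  names(sensors) <- names(recording$sensors)
  structure(list(fs = fs, participant_id = recording$participant_id,
                 sensors = sensors),
            class = "angle_series")
}

# complementary filter: tilt[t] = w*(tilt[t-1] + gyr[t]*dt) + (1-w)*tilt_acc[t]
complementary <- function(tilt_acc, gyr, dt, w) {
  u <- w * gyr * dt + (1 - w) * tilt_acc
  init <- tilt_acc[1L]
  out <- stats::filter(u[-1L], w, method = "recursive", init = init)
  c(init, as.numeric(out))
}

#' Write an angle series to per-sensor CSV files
#'
#' Columns `t_s, sag_deg, cor_deg, heading_deg`, one file per sensor named
#' `{participant}_{sensor}_angles.csv`.
#'
#' @param angles an `angle_series`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_angles <- function(angles, dir) {
  stopifnot(inherits(angles, "angle_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sn in names(angles$sensors)) {
    data.table::fwrite(
      angles$sensors[[sn]],
      file.path(dir, sprintf("%s_%s_angles.csv", angles$participant_id, sn))
    )
  }
  invisible(dir)
}
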