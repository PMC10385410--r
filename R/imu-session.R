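#' gdcr: adaptive control of the gait detection and classification rate
#'
#' Detects gait events from raw ankle-worn IMU logs, classifies them
#' against an acceleration threshold, and adaptively steers the resulting
#' gait detection and classification rate (GDCR) toward a target.
#'
#' @section Raw units:
#' All thresholds and signals are kept in raw sensor counts (LSB):
#' 16,384 counts per g (9.81 m/s^2) for the accelerometer and 131 counts
#' per deg/s for the gyroscope.  [unit_convert()] translates to physical
#' units on request; nothing converts implicitly.
#'
#' @keywords internal
"_PACKAGE"

IMU_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

#' Construct an IMU session
#'
#' A session is a time-ordered table of raw 6-axis samples: seconds from
#' session start `t` plus integer accelerometer (`ax`, `ay`, `az`) and
#' gyroscope (`gx`, `gy`, `gz`) counts, nominally at 30 Hz.
#'
#' @param data data.frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @return The validated data.frame with class `imu_session`.
#' @export
imu_session <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(IMU_COLUMNS, names(data))
  if (length(missing) > 0L) {
    stop("IMU session is missing column(s): ", paste(missing, collapse = ", "))
  }
  data <- data[IMU_COLUMNS]
  if (nrow(data) == 0L) stop("IMU session has no samples")
  if (any(data$t < 0)) stop("sample times must be non-negative")
  if (is.unsorted(data$t, strictly = TRUE)) {
    stop("sample times must be strictly increasing")
  }
  for (col in IMU_COLUMNS[-1]) {
    v <- data[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v))) {
      stop("column '", col, "' must hold integer sensor counts")
    }
  }
  class(data) <- c("imu_session", "data.frame")
  data
}

#' @export
print.imu_session <- function(x, ...) {
  dur <- x$t[nrow(x)] - x$t[1]
  cat(sprintf("<imu_session> %d samples spanning %.2f s (~%.1f Hz)\n",
              nrow(x), dur, if (dur > 0) (nrow(x) - 1) / dur else NA_real_))
  invisible(x)
}

#' Read / write raw IMU session CSV
#'
#' The interchange format is a plain comma-separated file with header
#' `t,ax,ay,az,gx,gy,gz`; `t` in seconds (decimal point `.`), the six
#' sensor columns integer raw counts.  Malformed rows are rejected with
#' the offending line number rather than coerced.
#'
#' @param path file path.
#' @return [read_imu_csv()] returns an [imu_session()].
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty IMU file: ", path)
  cols <- strsplit(header, ",", fixed = TRUE)[[1]]
  missing <- setdiff(IMU_COLUMNS, cols)
  if (length(missing) > 0L) {
    stop("IMU CSV header is missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("IMU file has a header but no samples: ", path)
  out <- data.frame(t = suppressWarnings(as.numeric(raw$t)))
  bad <- which(is.na(out$t))
  if (length(bad) > 0L) {
    stop("malformed time value at line ", bad[1] + 1L, " of ", path)
  }
  for (col in IMU_COLUMNS[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad) > 0L) {
      stop("malformed integer value in column '", col, "' at line ",
           bad[1] + 1L, " of ", path)
    }
    out[[col]] <- v
  }
  imu_session(out)
}

#' @rdname read_imu_csv
#' @param session an [imu_session()].
#' @export
write_imu_csv <- function(session, path) {
  stopifnot(inherits(session, "imu_session"))
  df <- as.data.frame(session)
  df[IMU_COLUMNS[-1]] <- lapply(df[IMU_COLUMNS[-1]], function(v) {
    format(v, scientific = FALSE, trim = TRUE)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standing-still calibration
#'
#' Before a session the wearer stands straight for a window (30 s by
#' default in the protocol) and the per-axis mean accelerometer counts in
#' that default position become the baseline; subtracting it removes both
#' mounting offset and gravity in the default orientation.
#'
#' @param samples an [imu_session()] (or data.frame with `ax`, `ay`, `az`)
#'   recorded while stationary.
#' @return object of class `calibration_profile` with fields
#'   `baseline_ax`, `baseline_ay`, `baseline_az`, `window_duration`.
#' @export
calibrate_baseline <- function(samples) {
  if (is.null(samples) || NROW(samples) == 0L) stop("no calibration data")
  stopifnot(all(c("ax", "ay", "az") %in% names(samples)))
  dur <- if ("t" %in% names(samples) && NROW(samples) > 1L) {
    diff(range(samples$t))
  } else {
    NROW(samples) / 30
  }
  calibration_profile(mean(samples$ax), mean(samples$ay), mean(samples$az),
                      window_duration = dur)
}

#' @rdname calibrate_baseline
#' @param baseline_ax,baseline_ay,baseline_az per-axis baseline counts.
#' @param window_duration seconds of standing data behind the baseline.
#' @export
calibration_profile <- function(baseline_ax, baseline_ay, baseline_az,
                                window_duration = 30) {
  stopifnot(window_duration > 0)
  structure(list(baseline_ax = baseline_ax, baseline_ay = baseline_ay,
                 baseline_az = baseline_az,
                 window_duration = window_duration),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> baseline (ax, ay, az) = (%.1f, %.1f, %.1f) counts over %.1f s\n",
              x$baseline_ax, x$baseline_ay, x$baseline_az, x$window_duration))
  invisible(x)
}

#' Sagittal-plane acceleration magnitude
#'
#' Magnitude of the baseline-subtracted acceleration in the sagittal
#' plane.  The gyro z axis is the medial-lateral axis, so the device x
#' and y accelerometer axes span the sagittal plane:
#' `sqrt((ax - baseline_ax)^2 + (ay - baseline_ay)^2)`.
#'
#' @param samples an [imu_session()] or any data.frame with `ax`, `ay`.
#' @param profile a [calibration_profile()] from the same mounting.
#' @return numeric vector of raw-count magnitudes, one per sample.
#' @export
accel_magnitude <- function(samples, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  sqrt((samples$ax - profile$baseline_ax)^2 +
       (samples$ay - profile$baseline_ay)^2)
}

#' Convert raw sensor counts to physical units
#'
#' @param value raw counts.
#' @param kind `"accel"` (to m/s^2, 16,384 counts per 9.81 m/s^2) or
#'   `"gyro"` (to deg/s, 131 counts per deg/s).
#' @return numeric vector in physical units.
#' @export
unit_convert <- function(value, kind = c("accel", "gyro")) {
  kind <- match.arg(kind)
  switch(kind,
         accel = value / 16384 * 9.81,
         gyro  = value / 131)
}
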