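# Synthetic cohort: virtual subjects carry a scaled-logistic
# GDCR-versus-AT curve per treadmill speed, the same family as the
# population model, with subject-level variation in amplitude (curve
# ceiling), midpoint (threshold where the curve halves) and rate
# (steepness).  The generator is calibrated so that the cohort-average
# GDCR over the algorithmic AT grid reproduces the published per-speed
# means at the five protocol speeds.

COHORT_SPEEDS <- c(1.0, 1.5, 2.0, 2.5, 3.0)
COHORT_TARGET_MEANS <- c(0.27, 0.45, 0.49, 0.52, 0.59)
# Per-speed curve ceilings; their mean, 0.720, anchors the population
# average GDCR at AT = 1000 underlying the normalization constant.
COHORT_AMPLITUDE_MEANS <- c(0.56, 0.67, 0.72, 0.77, 0.88)

#' Cohort generator parameters
#'
#' Distribution parameters for the virtual cohort.  Subjects share one
#' logistic rate and draw a common amplitude offset and a common midpoint
#' offset applied to the per-speed means; amplitudes are non-decreasing
#' in speed (faster walking gives a stronger swing signal).
#'
#' @param n_subjects cohort size.
#' @param speeds calibrated treadmill speeds, km/h.
#' @param amplitude_mean per-speed mean curve ceiling in \[0, 1\].
#' @param amplitude_sd between-subject SD of the ceiling offset.
#' @param midpoint_mean per-speed mean curve midpoint, raw counts; if
#'   `NULL` they must be supplied by [calibrate_generator()].
#' @param midpoint_sd between-subject SD of the midpoint offset, counts.
#' @param rate_meanlog,rate_sdlog log-normal parameters of the logistic
#'   rate (per count); defaults centre on the population rate 0.0009.
#' @param leg_asymmetry amplitude decrement applied to right-leg
#'   subjects (0 disables the left/right asymmetry, the default).
#' @param seed integer seed controlling cohort sampling.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 25,
                          speeds = COHORT_SPEEDS,
                          amplitude_mean = COHORT_AMPLITUDE_MEANS,
                          amplitude_sd = 0.05,
                          midpoint_mean = NULL,
                          midpoint_sd = 400,
                          rate_meanlog = log(LOGISTIC_SLOPE),
                          rate_sdlog = 0.1,
                          leg_asymmetry = 0,
                          seed = 7L) {
  stopifnot(n_subjects >= 1, amplitude_sd >= 0, midpoint_sd >= 0,
            length(amplitude_mean) == length(speeds))
  if (!is.null(midpoint_mean)) {
    stopifnot(length(midpoint_mean) == length(speeds))
  }
  structure(list(n_subjects = as.integer(n_subjects), speeds = speeds,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 midpoint_mean = midpoint_mean,
                 midpoint_sd = midpoint_sd,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 leg_asymmetry = leg_asymmetry,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

new_virtual_subject <- function(id, leg, speeds, amplitude, midpoint, rate) {
  stopifnot(all(amplitude >= 0 & amplitude <= 1),
            all(midpoint > 1000 & midpoint < 15000), rate > 0,
            !is.unsorted(amplitude))
  structure(list(subject_id = id, leg = leg, speeds = speeds,
                 amplitude = amplitude, midpoint = midpoint, rate = rate),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("<virtual_subject> %s (%s leg): amplitude %.2f-%.2f, midpoint %.0f-%.0f, rate %.5f\n",
              x$subject_id, x$leg, min(x$amplitude), max(x$amplitude),
              min(x$midpoint), max(x$midpoint), x$rate))
  invisible(x)
}

subject_from_quantiles <- function(params, id, leg, q_amp, q_mid, q_rate) {
  amp_off <- stats::qnorm(q_amp, 0, params$amplitude_sd)
  mid_off <- stats::qnorm(q_mid, 0, params$midpoint_sd)
  rate <- stats::qlnorm(q_rate, params$rate_meanlog, params$rate_sdlog)
  amp <- params$amplitude_mean + amp_off
  if (identical(leg, "right")) amp <- amp - params$leg_asymmetry
  amp <- cummax(pmin(pmax(amp, 0.02), 1))
  mid <- pmin(pmax(params$midpoint_mean + mid_off, 1001), 14999)
  new_virtual_subject(id, leg, params$speeds, amp, mid, rate)
}

#' Draw a single virtual subject
#'
#' Draws one subject from the parameter distributions using the current
#' RNG state.  Cohorts should be drawn with [sample_cohort()], which
#' balances the draw across subjects.
#'
#' @param params a [cohort_params()] with midpoints set (see
#'   [calibrate_generator()]).
#' @param id subject identifier.
#' @param leg `"left"` or `"right"`.
#' @return object of class `virtual_subject`.
#' @export
sample_subject <- function(params, id = "S01", leg = "left") {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(params$midpoint_mean)) {
    stop("cohort params carry no midpoints; run calibrate_generator() first")
  }
  subject_from_quantiles(params, id, leg,
                         stats::runif(1), stats::runif(1), stats::runif(1))
}

#' Draw a calibrated virtual cohort
#'
#' Samples `n_subjects` subjects with a randomized Latin hypercube over
#' the three subject-level factors (amplitude offset, midpoint offset,
#' rate), so even a 25-subject cohort covers the parameter distributions
#' evenly and its average curve sits close to the calibrated population
#' curve.  Fully deterministic given `params$seed`.
#'
#' @inheritParams sample_subject
#' @return list of `virtual_subject` objects, alternating left/right leg.
#' @export
sample_cohort <- function(params = calibrate_generator()) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(params$midpoint_mean)) {
    stop("cohort params carry no midpoints; run calibrate_generator() first")
  }
  n <- params$n_subjects
  set.seed(params$seed)
  q <- lhs::randomLHS(n, 3)
  lapply(seq_len(n), function(i) {
    subject_from_quantiles(params, sprintf("S%02d", i),
                           if (i %% 2L == 1L) "left" else "right",
                           q[i, 1], q[i, 2], q[i, 3])
  })
}

#' Subject GDCR curve with cross-speed interpolation
#'
#' Evaluates the subject's scaled-logistic curve
#' `amplitude * plogis(rate * (midpoint - AT))` at the two calibrated
#' speeds bracketing `speed` and interpolates the values linearly in
#' speed.  Strictly decreasing in AT; speeds outside the calibrated range
#' are clamped with a warning.
#'
#' @param subject a `virtual_subject`.
#' @param AT threshold value(s), raw counts.
#' @param speed walking speed, km/h.
#' @return predicted GDCR value(s) in \[0, 1\].
#' @export
subject_gdcr <- function(subject, AT, speed) {
  stopifnot(inherits(subject, "virtual_subject"), length(speed) == 1L)
  speeds <- subject$speeds
  if (speed < min(speeds) || speed > max(speeds)) {
    warning("speed ", speed, " km/h outside the calibrated range; clamped")
    speed <- min(max(speed, min(speeds)), max(speeds))
  }
  node_curve <- function(k) {
    subject$amplitude[k] *
      stats::plogis(subject$rate * (subject$midpoint[k] - AT))
  }
  hi <- which(speeds >= speed)[1]
  if (speeds[hi] == speed) return(node_curve(hi))
  lo <- hi - 1L
  w <- (speeds[hi] - speed) / (speeds[hi] - speeds[lo])
  w * node_curve(lo) + (1 - w) * node_curve(hi)
}

# Expected cohort-average GDCR over an AT grid at one speed, integrating
# the midpoint and rate distributions by mid-quantile quadrature (the
# amplitude enters linearly, so its mean is exact).
expected_grid_mean <- function(amp_mean, mid_mean, params, grid) {
  mid_nodes <- if (params$midpoint_sd > 0) {
    stats::qnorm((seq_len(15) - 0.5) / 15, mid_mean, params$midpoint_sd)
  } else {
    mid_mean
  }
  rate_nodes <- if (params$rate_sdlog > 0) {
    stats::qlnorm((seq_len(7) - 0.5) / 7, params$rate_meanlog,
                  params$rate_sdlog)
  } else {
    exp(params$rate_meanlog)
  }
  acc <- 0
  for (m in mid_nodes) {
    for (r in rate_nodes) {
      acc <- acc + mean(stats::plogis(r * (m - grid)))
    }
  }
  amp_mean * acc / (length(mid_nodes) * length(rate_nodes))
}

#' Calibrate the cohort generator to per-speed mean GDCRs
#'
#' Solves for the per-speed midpoint means so that the expected
#' cohort-average GDCR over the algorithmic AT grid (1000..15,000 step
#' 10) matches the published per-speed means (0.27, 0.45, 0.49, 0.52,
#' 0.59 at 1.0..3.0 km/h by default).
#'
#' @param target_means per-speed mean GDCR over the AT grid, in (0, 1).
#' @param params a [cohort_params()]; its `midpoint_mean` is replaced.
#' @param grid AT grid over which the means are taken.
#' @param tol admissible residual per speed.
#' @return the calibrated `cohort_params`.
#' @export
calibrate_generator <- function(target_means = COHORT_TARGET_MEANS,
                                params = cohort_params(),
                                grid = at_domain_grid(),
                                tol = 0.02) {
  stopifnot(inherits(params, "cohort_params"),
            length(target_means) == length(params$speeds),
            all(target_means > 0 & target_means < 1))
  midpoints <- vapply(seq_along(params$speeds), function(k) {
    f <- function(m) {
      expected_grid_mean(params$amplitude_mean[k], m, params, grid) -
        target_means[k]
    }
    lo <- 1001
    hi <- 14999
    if (f(lo) > 0 || f(hi) < 0) {
      stop(sprintf(paste0("target mean %.3f at %.1f km/h is unattainable ",
                          "with amplitude %.2f (achievable range %.3f-%.3f)"),
                   target_means[k], params$speeds[k],
                   params$amplitude_mean[k],
                   f(lo) + target_means[k], f(hi) + target_means[k]))
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
  }, numeric(1))
  params$midpoint_mean <- midpoints
  residual <- vapply(seq_along(params$speeds), function(k) {
    expected_grid_mean(params$amplitude_mean[k], midpoints[k], params, grid) -
      target_means[k]
  }, numeric(1))
  if (any(abs(residual) > tol)) {
    stop("calibration residuals exceed tolerance: ",
         paste(sprintf("%.4f", residual), collapse = ", "))
  }
  attr(params, "calibration_residual") <- residual
  params
}

#' Synthesize a raw 30 Hz walking session for a virtual subject
#'
#' Emulates one treadmill session at 90 steps/min cadence: 45 swings per
#' minute on the instrumented leg.  Each swing is a rectangular gyro-z
#' pulse (8 samples, peak uniform in 16,000..26,000 counts, always above
#' the default GT of 15,000) during which the sagittal acceleration is
#' held so that its mean magnitude over the pulse equals a per-swing draw
#' from the subject's GDCR curve at this speed, by inverse-survival
#' sampling: the probability that a swing's mean magnitude exceeds any AT
#' in the algorithmic domain equals `subject_gdcr(subject, AT, speed)`
#' exactly.  The standing baseline carries gravity on the y axis
#' (16,384 counts) plus small sensor noise.
#'
#' @inheritParams subject_gdcr
#' @param duration_s session length, seconds.
#' @param sample_rate_hz sampling rate.
#' @param cadence_spm step cadence (both legs), steps per minute.
#' @param noise_sd baseline sensor noise SD, counts.
#' @return an [imu_session()].
#' @export
synthesize_imu_session <- function(subject, speed, duration_s = 60,
                                   sample_rate_hz = 30, cadence_spm = 90,
                                   noise_sd = 30) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * sample_rate_hz)
  n_swings <- floor(duration_s * cadence_spm / 60 / 2)
  spacing <- round(sample_rate_hz * 60 / (cadence_spm / 2))
  pulse_len <- 8L
  baseline <- c(ax = 0, ay = 16384, az = 0)

  ax <- round(stats::rnorm(n, baseline["ax"], noise_sd))
  ay <- round(stats::rnorm(n, baseline["ay"], noise_sd))
  az <- round(stats::rnorm(n, baseline["az"], noise_sd))
  gx <- round(stats::rnorm(n, 0, noise_sd * 2))
  gy <- round(stats::rnorm(n, 0, noise_sd * 2))
  gz <- round(stats::rnorm(n, 0, noise_sd * 3))

  peaks <- round(stats::runif(n_swings, 16000, 26000))
  mags <- draw_swing_magnitudes(subject, speed, n_swings)
  for (j in seq_len(n_swings)) {
    s <- (j - 1L) * spacing + 10L
    idx <- s:(s + pulse_len - 1L)
    gz[idx] <- peaks[j]
    # constant sagittal deviation at 45 degrees: per-sample magnitude
    # equals the drawn mean exactly
    ax[idx] <- round(baseline["ax"] + mags[j] / sqrt(2))
    ay[idx] <- round(baseline["ay"] + mags[j] / sqrt(2))
  }
  imu_session(data.frame(t = (seq_len(n) - 1L) / sample_rate_hz,
                         ax = ax, ay = ay, az = az,
                         gx = gx, gy = gy, gz = gz))
}

# Inverse-survival draw of per-swing mean sagittal magnitudes: solves
# subject_gdcr(M) = U per swing so that P(M > AT) reproduces the curve
# over the algorithmic AT domain; swings falling outside the curve's
# reach become sub-1000 (always-bad) or supra-domain (always-good) draws.
draw_swing_magnitudes <- function(subject, speed, n_swings) {
  u <- stats::runif(n_swings)
  s_lo <- subject_gdcr(subject, 1000, speed)   # survival at easiest AT
  s_hi <- subject_gdcr(subject, 20000, speed)  # survival beyond the sweep
  vapply(u, function(ui) {
    if (ui >= s_lo) return(stats::runif(1, 200, 900))
    if (ui <= s_hi) return(20000)
    stats::uniroot(function(m) subject_gdcr(subject, m, speed) - ui,
                   c(1000, 20000), tol = 1e-6)$root
  }, numeric(1))
}

#' Synthesize a standing calibration recording
#'
#' Thirty seconds (by default) of stationary samples: gravity on the y
#' axis plus sensor noise, for feeding [calibrate_baseline()].
#'
#' @inheritParams synthesize_imu_session
#' @export
synthesize_standing <- function(duration_s = 30, sample_rate_hz = 30,
                                noise_sd = 30) {
  n <- round(duration_s * sample_rate_hz)
  imu_session(data.frame(t = (seq_len(n) - 1L) / sample_rate_hz,
                         ax = round(stats::rnorm(n, 0, noise_sd)),
                         ay = round(stats::rnorm(n, 16384, noise_sd)),
                         az = round(stats::rnorm(n, 0, noise_sd)),
                         gx = round(stats::rnorm(n, 0, noise_sd)),
                         gy = round(stats::rnorm(n, 0, noise_sd)),
                         gz = round(stats::rnorm(n, 0, noise_sd))))
}

#' Write a synthetic cohort to per-session CSV files
#'
#' Synthesizes one session per subject and speed, writes each as an IMU
#' CSV, and returns (and writes) a manifest table
#' `subject_id,leg,speed,file,seed`.
#'
#' @param cohort list of `virtual_subject`s from [sample_cohort()].
#' @param dir output directory (created if needed).
#' @param speeds session speeds, km/h.
#' @param seed integer seed for the session synthesis.
#' @param duration_s session length, seconds.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort_sessions <- function(cohort, dir, speeds = COHORT_SPEEDS,
                                  seed = 1L, duration_s = 60) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rows <- list()
  for (subject in cohort) {
    for (speed in speeds) {
      file <- sprintf("%s_speed%.1f.csv", subject$subject_id, speed)
      session <- synthesize_imu_session(subject, speed,
                                        duration_s = duration_s)
      write_imu_csv(session, file.path(dir, file))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = subject$subject_id, leg = subject$leg,
                   speed = speed, file = file, seed = seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
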