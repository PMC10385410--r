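#' Detection / classification threshold pair
#'
#' `GT` is the gyroscopic threshold (raw gyro counts) that opens a gait
#' detection range; `AT` is the acceleration threshold (raw accel counts)
#' that the mean sagittal magnitude over a range must exceed for the gait
#' to count as good.  The studied ranges are AT in \[1000, 20000\] and GT
#' in \[15000, 25000\]; values outside warn but are accepted.
#'
#' @param AT acceleration threshold, raw accelerometer counts.
#' @param GT gyroscopic threshold, raw gyroscope counts.
#' @param min_duration minimum number of samples a detection range must
#'   span (shorter runs are discarded).
#' @param merge_gap runs separated by fewer than this many sub-threshold
#'   samples are merged, so one noisy swing is not double counted.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(AT = 6000, GT = 15000,
                             min_duration = 2L, merge_gap = 5L) {
  stopifnot(is.numeric(AT), is.numeric(GT),
            min_duration >= 1L, merge_gap >= 0L)
  if (AT < 1000 || AT > 20000) {
    warning("AT = ", AT, " is outside the studied range [1000, 20000]")
  }
  if (GT < 15000 || GT > 25000) {
    warning("GT = ", GT, " is outside the studied range [15000, 25000]")
  }
  structure(list(AT = AT, GT = GT,
                 min_duration = as.integer(min_duration),
                 merge_gap = as.integer(merge_gap)),
            class = "threshold_config")
}

#' Detect gait ranges from angular velocity
#'
#' A gait detection range is a maximal contiguous run of samples whose
#' gyro z count is strictly above `GT` (the swing phase of the
#' instrumented leg).  Runs separated by fewer than `merge_gap`
#' sub-threshold samples are merged, then runs shorter than
#' `min_duration` samples are dropped.
#'
#' @param session an [imu_session()].
#' @param config a [threshold_config()].
#' @return data.frame of class `gait_ranges` with integer columns
#'   `start_index`, `end_index` (inclusive, ordered, disjoint) and
#'   placeholder columns `mean_accel_magnitude`, `classified_good`
#'   filled by [classify_ranges()].
#' @export
detect_gait_ranges <- function(session, config = threshold_config()) {
  stopifnot(inherits(session, "imu_session"),
            inherits(config, "threshold_config"))
  above <- session$gz > config$GT
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) > 0L && length(starts) > 1L && config$merge_gap > 0L) {
    gaps <- starts[-1] - ends[-length(ends)] - 1L
    merged_start <- integer(0)
    merged_end <- integer(0)
    cur_s <- starts[1]
    cur_e <- ends[1]
    for (i in seq_along(gaps)) {
      if (gaps[i] < config$merge_gap) {
        cur_e <- ends[i + 1]
      } else {
        merged_start <- c(merged_start, cur_s)
        merged_end <- c(merged_end, cur_e)
        cur_s <- starts[i + 1]
        cur_e <- ends[i + 1]
      }
    }
    starts <- c(merged_start, cur_s)
    ends <- c(merged_end, cur_e)
  }
  long_enough <- (ends - starts + 1L) >= config$min_duration
  starts <- as.integer(starts[long_enough])
  ends <- as.integer(ends[long_enough])
  out <- data.frame(start_index = starts,
                    end_index = ends,
                    mean_accel_magnitude = rep(NA_real_, length(starts)),
                    classified_good = rep(NA, length(starts)))
  class(out) <- c("gait_ranges", "data.frame")
  out
}

#' Classify detected gait ranges
#'
#' Fills in the mean sagittal acceleration magnitude over each detection
#' range and the good-gait verdict: a gait is good when that mean is
#' strictly above `AT`.
#'
#' @inheritParams detect_gait_ranges
#' @param ranges a `gait_ranges` table from [detect_gait_ranges()].
#' @param profile a [calibration_profile()].
#' @return the `gait_ranges` table with `mean_accel_magnitude` and
#'   `classified_good` filled in.
#' @export
classify_ranges <- function(ranges, session, profile,
                            config = threshold_config()) {
  stopifnot(inherits(ranges, "gait_ranges"),
            inherits(session, "imu_session"))
  if (nrow(ranges) == 0L) return(ranges)
  if (any(ranges$start_index < 1L) || any(ranges$end_index > nrow(session))) {
    stop("detection range indices fall outside the session")
  }
  mag <- accel_magnitude(session, profile)
  ranges$mean_accel_magnitude <- vapply(seq_len(nrow(ranges)), function(i) {
    mean(mag[ranges$start_index[i]:ranges$end_index[i]])
  }, numeric(1))
  ranges$classified_good <- ranges$mean_accel_magnitude > config$AT
  ranges
}

#' Gait detection and classification rate
#'
#' GDCR is the fraction of detected gaits classified good.  With zero
#' detections the rate is undefined (`NA`), deliberately distinct from
#' zero: no detections carries no evidence about gait quality, and a
#' controller fed `NA` leaves its state untouched.
#'
#' @param ranges a classified `gait_ranges` table.
#' @return list of class `gdcr_result`: `detected`, `classified`, `gdcr`.
#' @export
compute_gdcr <- function(ranges) {
  stopifnot(inherits(ranges, "gait_ranges"))
  detected <- nrow(ranges)
  classified <- if (detected > 0L) sum(ranges$classified_good) else 0L
  structure(list(detected = detected,
                 classified = as.integer(classified),
                 gdcr = if (detected > 0L) classified / detected else NA_real_),
            class = "gdcr_result")
}

#' @export
print.gdcr_result <- function(x, ...) {
  cat(sprintf("<gdcr_result> %d detected, %d classified good, GDCR = %s\n",
              x$detected, x$classified,
              if (is.na(x$gdcr)) "undefined" else sprintf("%.4f", x$gdcr)))
  invisible(x)
}

#' Threshold grids used throughout
#'
#' `at_grid()` is the full sweep grid of acceleration thresholds (1901
#' points, 1000 to 20,000 every 10); `at_domain_grid()` restricts it to
#' the algorithmic domain 1000 to 15,000 (1401 points) on which the
#' logistic model lives; `gt_grid()` is the gyroscopic sweep (21 points,
#' 15,000 to 25,000 every 500).
#'
#' @param from,to,by grid limits and step, raw counts.
#' @return numeric vector of thresholds.
#' @export
at_grid <- function(from = 1000, to = 20000, by = 10) seq(from, to, by = by)

#' @rdname at_grid
#' @export
at_domain_grid <- function(from = 1000, to = 15000, by = 10) seq(from, to, by = by)

#' @rdname at_grid
#' @export
gt_grid <- function(from = 15000, to = 25000, by = 500) seq(from, to, by = by)

#' GDCR as a function of a swept threshold
#'
#' Sweeps either AT (with GT held fixed; detection ranges are computed
#' once since detection depends only on GT) or GT (ranges recomputed per
#' grid point) and records the session GDCR at each grid value.
#'
#' @inheritParams classify_ranges
#' @param sweep `"AT"` or `"GT"`.
#' @param grid strictly increasing threshold values.
#' @param fixed_other the non-swept threshold; defaults to GT = 15,000
#'   for AT sweeps and AT = 6000 for GT sweeps.
#' @param speed walking speed in km/h attached as metadata (optional).
#' @param config base [threshold_config()] supplying the run-length rules.
#' @return data.frame of class `gdcr_curve` with columns `grid`, `value`
#'   and attributes `swept`, `fixed_other`, `speed`.
#' @export
gdcr_curve <- function(session, profile, sweep = c("AT", "GT"),
                       grid = NULL, fixed_other = NULL, speed = NA_real_,
                       config = threshold_config()) {
  sweep <- match.arg(sweep)
  if (is.null(grid)) grid <- if (sweep == "AT") at_grid() else gt_grid()
  if (length(grid) == 0L) stop("empty threshold grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (is.null(fixed_other)) fixed_other <- if (sweep == "AT") 15000 else 6000
  if (sweep == "AT") {
    cfg <- config
    cfg$GT <- fixed_other
    ranges <- classify_ranges(detect_gait_ranges(session, cfg),
                              session, profile, cfg)
    values <- if (nrow(ranges) == 0L) {
      rep(NA_real_, length(grid))
    } else {
      vapply(grid, function(at) mean(ranges$mean_accel_magnitude > at),
             numeric(1))
    }
  } else {
    values <- vapply(grid, function(gt) {
      cfg <- config
      cfg$GT <- gt
      cfg$AT <- fixed_other
      ranges <- classify_ranges(detect_gait_ranges(session, cfg),
                                session, profile, cfg)
      compute_gdcr(ranges)$gdcr
    }, numeric(1))
  }
  new_gdcr_curve(grid, values, sweep, fixed_other, speed)
}

new_gdcr_curve <- function(grid, values, swept, fixed_other, speed) {
  stopifnot(length(grid) == length(values))
  out <- data.frame(grid = grid, value = values)
  attr(out, "swept") <- swept
  attr(out, "fixed_other") <- fixed_other
  attr(out, "speed") <- speed
  class(out) <- c("gdcr_curve", "data.frame")
  out
}

#' @export
print.gdcr_curve <- function(x, ...) {
  cat(sprintf("<gdcr_curve> %s sweep, %d points, fixed %s = %s, speed = %s km/h\n",
              attr(x, "swept"), nrow(x),
              if (attr(x, "swept") == "AT") "GT" else "AT",
              format(attr(x, "fixed_other")), format(attr(x, "speed"))))
  invisible(x)
}

#' Read / write a GDCR curve CSV
#'
#' Two-column CSV (`grid,value`) preceded by comment lines carrying the
#' sweep metadata, e.g. `# swept=AT`, `# fixed_GT=15000`, `# speed=2`.
#'
#' @param curve a `gdcr_curve`.
#' @param path file path.
#' @export
write_gdcr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "gdcr_curve"))
  swept <- attr(curve, "swept")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# swept=%s", swept),
               sprintf("# fixed_%s=%s", if (swept == "AT") "GT" else "AT",
                       format(attr(curve, "fixed_other"))),
               sprintf("# speed=%s", format(attr(curve, "speed")))), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gdcr_curve
#' @export
read_gdcr_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, invert = TRUE,
                                            value = TRUE)))
  swept <- meta[["swept"]]
  fixed_key <- if (identical(swept, "AT")) "fixed_GT" else "fixed_AT"
  new_gdcr_curve(df$grid, df$value, swept,
                 as.numeric(meta[[fixed_key]]),
                 as.numeric(meta[["speed"]]))
}
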