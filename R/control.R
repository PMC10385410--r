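#' Controller constants
#'
#' The fixed constants of the adaptive GDCR controller.  Defaults are the
#' calibrated population values: the initialization multiplier 1.11 (the
#' population's GDCR at AT = 1000 over its GDCR at AT = 6000), the
#' population average GDCR 0.720 at AT = 1000, the target cap 0.9, the
#' 0.01 back-off applied when the personal coefficient falls below the
#' cap, and the initialization condition AT = 6000 at 2 km/h.
#'
#' @param init_multiplier multiplier turning the initialization GDCR into
#'   the first personal coefficient.
#' @param base_gdcr population average GDCR at AT = 1000.
#' @param target_cap highest GDCR the controller will aim for.
#' @param target_backoff margin subtracted from the personal coefficient
#'   when it cannot reach the cap.
#' @param target_floor lowest admissible target.
#' @param init_AT,init_speed initialization threshold (counts) and
#'   walking speed (km/h).
#' @param at_range admissible AT interval, raw counts.
#' @param exact use the exact algebraic inverse of the personalized
#'   logistic (slope 10/0.009, intercept 1000 + 7.009/0.0009); `FALSE`
#'   reproduces the printed rounded constants 1111.11 and 8787.77.
#' @return list of class `gdcr_constants`.
#' @export
gdcr_constants <- function(init_multiplier = 1.11,
                           base_gdcr = 0.720,
                           target_cap = 0.9,
                           target_backoff = 0.01,
                           target_floor = 0.01,
                           init_AT = 6000,
                           init_speed = 2.0,
                           at_range = AT_DOMAIN,
                           exact = TRUE) {
  structure(list(init_multiplier = init_multiplier,
                 base_gdcr = base_gdcr,
                 target_cap = target_cap,
                 target_backoff = target_backoff,
                 target_floor = target_floor,
                 init_AT = init_AT,
                 init_speed = init_speed,
                 at_range = at_range,
                 exact = exact),
            class = "gdcr_constants")
}

#' Closed-form threshold inversion constants
#'
#' The personalized curve `G_p(AT) = C_p / (1 + exp(0.0009*(AT-1000) -
#' 7.009))` inverts algebraically to `AT = slope * ln(C_p/G_t - 1) +
#' intercept` with slope `10/0.009` and intercept `1000 + 7.009/0.0009`.
#' The rounded printed form uses 1111.11 and 8787.77.
#'
#' @param exact exact constants (default) or the printed rounded ones.
#' @return named numeric vector `c(slope, intercept)`.
#' @export
inversion_constants <- function(exact = TRUE) {
  if (exact) {
    c(slope = 1 / LOGISTIC_SLOPE,
      intercept = 1000 + LOGISTIC_OFFSET / LOGISTIC_SLOPE)
  } else {
    c(slope = 1111.11, intercept = 8787.77)
  }
}

#' Initial personal coefficient
#'
#' The first personal coefficient scales the observed GDCR at the
#' initialization condition (AT = 6000, 2 km/h) by the population ratio
#' 1.11 (average GDCR at AT = 1000 over average GDCR at AT = 6000).
#'
#' @param observed_gdcr GDCR measured at the initialization condition.
#' @param constants a [gdcr_constants()].
#' @return the coefficient `C_p1`.
#' @export
initial_coefficient <- function(observed_gdcr, constants = gdcr_constants()) {
  if (is.na(observed_gdcr)) stop("no detections during initialization")
  constants$init_multiplier * observed_gdcr
}

#' Update the personal coefficient from an observed GDCR
#'
#' `C_pn = base_gdcr * observed / G_nor(AT)`, the ratio of observed to
#' expected GDCR scaled back to the population anchor; algebraically
#' equal to `observed / G(AT)`.
#'
#' @inheritParams initial_coefficient
#' @param AT threshold at which the GDCR was observed, raw counts.
#' @return updated coefficient, or `NA` if the observation is undefined.
#' @export
update_coefficient <- function(observed_gdcr, AT,
                               constants = gdcr_constants()) {
  if (is.na(observed_gdcr)) return(NA_real_)
  constants$base_gdcr * observed_gdcr / normalized_curve(AT, constants)
}

#' Population-scaled and personalized logistic curves
#'
#' `normalized_curve()` is the population curve scaled by the average
#' GDCR at AT = 1000 (`G_nor = 0.720 * G`); `personalized_curve()` scales
#' by a personal coefficient (`G_p = C_p * G`).  Predicted values above 1
#' are reported as-is: they are model predictions, not observable rates.
#'
#' @inheritParams update_coefficient
#' @param C_p personal coefficient.
#' @return predicted GDCR value(s).
#' @export
normalized_curve <- function(AT, constants = gdcr_constants()) {
  constants$base_gdcr * logistic_gdcr(AT)
}

#' @rdname normalized_curve
#' @export
personalized_curve <- function(AT, C_p) {
  C_p * logistic_gdcr(AT)
}

#' Invert the personalized curve for a target GDCR
#'
#' Solves `G_p(AT) = G_t` in closed form:
#' `AT = slope * ln(C_p/G_t - 1) + intercept`, clamped to the admissible
#' AT interval.  A target at or above the personal coefficient is
#' unreachable, so the threshold drops to its easiest value (the lower
#' clamp) with a warning.
#'
#' @param G_t target GDCR, in (0, 1).
#' @inheritParams normalized_curve
#' @inheritParams initial_coefficient
#' @return acceleration threshold in `constants$at_range`.
#' @export
invert_threshold <- function(G_t, C_p, constants = gdcr_constants()) {
  if (G_t <= 0) stop("target GDCR must be positive")
  lo <- constants$at_range[1]
  hi <- constants$at_range[2]
  if (G_t >= C_p) {
    warning("target GDCR ", format(G_t), " is unreachable for C_p = ",
            format(C_p), "; easiest threshold used")
    return(lo)
  }
  k <- inversion_constants(constants$exact)
  at <- k[["slope"]] * log(C_p / G_t - 1) + k[["intercept"]]
  min(max(at, lo), hi)
}

#' Target rule
#'
#' The controller aims for a GDCR of 0.9 when the personal coefficient
#' supports it, and otherwise for 0.01 below the coefficient (floored at
#' 0.01).  A coefficient of exactly 0.9 is treated as reaching the cap.
#'
#' @inheritParams invert_threshold
#' @return target GDCR `G_target`.
#' @export
target_rule <- function(C_p, constants = gdcr_constants()) {
  if (C_p >= constants$target_cap) {
    constants$target_cap
  } else {
    max(C_p - constants$target_backoff, constants$target_floor)
  }
}

new_controller_state <- function(C_p, G_target, AT, step_index, history,
                                 constants) {
  structure(list(C_p = C_p, G_target = G_target, AT = AT,
                 step_index = step_index, history = history,
                 constants = constants),
            class = "gdcr_controller")
}

#' Initialize the adaptive controller
#'
#' Runs the initial-setting phase: the GDCR observed at AT = 6000 and
#' 2 km/h becomes `C_p1 = 1.11 * observed`, the target rule fixes
#' `G_target`, and the closed-form inversion yields the first working
#' threshold.
#'
#' @param observed_gdcr GDCR measured at the initialization condition
#'   (undefined/`NA` is an error: the controller cannot start without a
#'   detection).
#' @inheritParams initial_coefficient
#' @return object of class `gdcr_controller` holding `C_p`, `G_target`,
#'   `AT`, `step_index` and a history table.
#' @export
run_initialization <- function(observed_gdcr, constants = gdcr_constants()) {
  C_p <- initial_coefficient(observed_gdcr, constants)
  G_target <- target_rule(C_p, constants)
  AT <- if (C_p <= 0) {
    constants$at_range[1]
  } else {
    suppressWarnings(invert_threshold(G_target, C_p, constants))
  }
  history <- data.frame(step = 0L, AT = constants$init_AT,
                        gdcr = observed_gdcr, C_p = C_p,
                        G_target = G_target)
  new_controller_state(C_p, G_target, AT, 0L, history, constants)
}

#' Advance the controller by one exercise session
#'
#' Applies the update in order: re-estimate the personal coefficient from
#' the session's observed GDCR at the current threshold, re-apply the
#' target rule, invert for the next threshold.  The controller adapts
#' once per session (a day's summarized exercise), never per stride.  An
#' undefined observation (`NA`, no detections) leaves the state unchanged
#' apart from bookkeeping.
#'
#' @param state a `gdcr_controller`.
#' @param observed_gdcr GDCR observed while exercising at `state$AT`.
#' @return the updated `gdcr_controller`.
#' @export
controller_step <- function(state, observed_gdcr) {
  stopifnot(inherits(state, "gdcr_controller"))
  constants <- state$constants
  if (is.na(observed_gdcr)) {
    return(state)  # no detections: no information, state untouched
  }
  at_used <- state$AT
  C_p <- update_coefficient(observed_gdcr, at_used, constants)
  G_target <- target_rule(C_p, constants)
  AT <- if (C_p <= 0) {
    constants$at_range[1]
  } else {
    suppressWarnings(invert_threshold(G_target, C_p, constants))
  }
  step_index <- state$step_index + 1L
  history <- rbind(state$history,
                   data.frame(step = step_index, AT = at_used,
                              gdcr = observed_gdcr, C_p = C_p,
                              G_target = G_target))
  new_controller_state(C_p, G_target, AT, step_index, history, constants)
}

#' @export
print.gdcr_controller <- function(x, ...) {
  cat(sprintf("<gdcr_controller> step %d: C_p = %.4f, G_target = %.3f, next AT = %.1f\n",
              x$step_index, x$C_p, x$G_target, x$AT))
  invisible(x)
}

#' Serialize / restore a controller history
#'
#' One JSON object per line with fields `step`, `AT`, `gdcr`, `C_p`,
#' `G_target`.
#'
#' @param state a `gdcr_controller`.
#' @param path file path.
#' @return [read_controller_history()] returns the history data.frame.
#' @export
write_controller_history <- function(state, path) {
  stopifnot(inherits(state, "gdcr_controller"))
  h <- state$history
  lines <- vapply(seq_len(nrow(h)), function(i) {
    jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_controller_history
#' @export
read_controller_history <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(ln) {
    as.data.frame(jsonlite::fromJSON(ln))
  })
  do.call(rbind, rows)
}
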