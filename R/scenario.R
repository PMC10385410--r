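# Virtual walking-speed scenarios and the three-way controller
# comparison.  Scenarios are session-wise speed sequences spanning the
# calibrated 1.0-3.0 km/h range; each simulated session observes the
# subject's GDCR at the current threshold and speed, and the method under
# test picks the next threshold.

SCENARIO_DESCRIPTIONS <- c(
  "linear increase",
  "linear decrease",
  "random within bounds",
  "sudden decrease during linear increase",
  "sudden increase during linear decrease",
  "linear increase after linear decrease (V shape)",
  "linear decrease - random - linear increase",
  "linear decrease - sudden increase - random",
  "random after linear increase")

#' Build a walking-speed scenario
#'
#' The nine scenarios combine linear ramps (spanning 1.0 to 3.0 km/h),
#' bounded random segments (uniform in \[1.5, 2.5\] km/h) and one-session
#' sudden jumps to the opposite extreme of the running trend, placed at
#' the midpoint session.  Random segments use the current RNG state, so
#' seed before calling for reproducibility.
#'
#' @param id scenario number, 1-9.
#' @param n_sessions number of exercise sessions.
#' @param random_bounds bounds of the random segments, km/h.
#' @return list of class `gait_scenario` with fields `id`, `speeds`,
#'   `n_sessions`, `description`.
#' @export
build_scenario <- function(id, n_sessions = 20,
                           random_bounds = c(1.5, 2.5)) {
  if (!id %in% 1:9) stop("scenario id must be in 1..9")
  stopifnot(n_sessions >= 4)
  n <- n_sessions
  ramp <- function(from, to, len) seq(from, to, length.out = len)
  rand <- function(len) stats::runif(len, random_bounds[1], random_bounds[2])
  mid <- floor(n / 2) + 1L
  h <- floor(n / 2)
  speeds <- switch(id,
    ramp(1, 3, n),
    ramp(3, 1, n),
    rand(n),
    { s <- ramp(1, 3, n); s[mid] <- 1.0; s },
    { s <- ramp(3, 1, n); s[mid] <- 3.0; s },
    { k <- ceiling((n + 1) / 2)
      c(ramp(3, 1, k), ramp(1, 3, n - k + 1L)[-1]) },
    { k <- floor(n / 3)
      c(ramp(3, 1, k), rand(n - 2L * k), ramp(1, 3, k)) },
    c(ramp(3, 1, h), 3.0, rand(n - h - 1L)),
    c(ramp(1, 3, h), rand(n - h)))
  structure(list(id = id, speeds = speeds, n_sessions = n,
                 description = SCENARIO_DESCRIPTIONS[id]),
            class = "gait_scenario")
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf("<gait_scenario> #%d (%s), %d sessions, speeds %.1f-%.1f km/h\n",
              x$id, x$description, x$n_sessions,
              min(x$speeds), max(x$speeds)))
  invisible(x)
}

# One session's GDCR observation.  Analytic mode reads the subject's
# curve directly (the virtual simulation is curve based); end-to-end
# mode synthesizes a raw session and runs the full detection pipeline.
observe_gdcr <- function(subject, AT, speed, mode, profile = NULL,
                         config = threshold_config()) {
  if (mode == "analytic") return(subject_gdcr(subject, AT, speed))
  session <- synthesize_imu_session(subject, speed)
  cfg <- config
  cfg$AT <- AT
  ranges <- classify_ranges(detect_gait_ranges(session, cfg),
                            session, profile, cfg)
  compute_gdcr(ranges)$gdcr
}

#' Run one control method through a scenario
#'
#' Simulates the closed loop: every session the subject walks at the
#' scenario speed with the method's current acceleration threshold, the
#' GDCR is observed, and the method chooses the next threshold.
#'
#' * `adaptive` -- the personalized-logistic controller
#'   ([run_initialization()], [controller_step()]); initialization
#'   measures the GDCR at AT = 6000 and 2 km/h before the scenario.
#' * `fixed` -- holds AT = 6000 throughout.
#' * `simple` -- starts at AT = 6000 and moves by 100 counts per session:
#'   up when the GDCR exceeds 0.95, down when it falls below 0.9.
#'
#' @param subject a `virtual_subject`.
#' @param scenario a `gait_scenario`.
#' @param method `"adaptive"`, `"fixed"` or `"simple"`.
#' @param constants controller constants ([gdcr_constants()]).
#' @param mode `"analytic"` (curve lookup, the default) or
#'   `"end_to_end"` (synthesized raw sessions through the detection
#'   pipeline).
#' @param profile calibration profile for end-to-end mode; defaults to
#'   the ideal standing baseline.
#' @return list of class `simulation_result`: `scenario_id`, `method`,
#'   `subject_id`, `trace` (session, speed, AT, gdcr, error) and
#'   `avg_error`, the mean absolute deviation of the observed GDCR from
#'   the 0.9 target.
#' @export
run_control <- function(subject, scenario,
                        method = c("adaptive", "fixed", "simple"),
                        constants = gdcr_constants(),
                        mode = c("analytic", "end_to_end"),
                        profile = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(scenario, "gait_scenario"))
  if (mode == "end_to_end" && is.null(profile)) {
    profile <- calibration_profile(0, 16384, 0)
  }
  target <- constants$target_cap
  at <- constants$init_AT
  state <- NULL
  if (method == "adaptive") {
    g0 <- observe_gdcr(subject, constants$init_AT, constants$init_speed,
                       mode, profile)
    state <- run_initialization(g0, constants)
    at <- state$AT
  }
  n <- scenario$n_sessions
  gdcr_trace <- numeric(n)
  at_trace <- numeric(n)
  for (s in seq_len(n)) {
    g <- observe_gdcr(subject, at, scenario$speeds[s], mode, profile)
    at_trace[s] <- at
    gdcr_trace[s] <- g
    at <- switch(method,
      adaptive = {
        state <- controller_step(state, g)
        state$AT
      },
      fixed = at,
      simple = {
        if (!is.na(g) && g > 0.95) {
          min(at + 100, constants$at_range[2])
        } else if (!is.na(g) && g < 0.9) {
          max(at - 100, constants$at_range[1])
        } else at
      })
  }
  err <- abs(gdcr_trace - target)
  structure(list(scenario_id = scenario$id, method = method,
                 subject_id = subject$subject_id,
                 trace = data.frame(session = seq_len(n),
                                    speed = scenario$speeds,
                                    AT = at_trace, gdcr = gdcr_trace,
                                    error = err),
                 avg_error = mean(err, na.rm = TRUE)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> scenario %d, %s method, subject %s: avg |GDCR - 0.9| = %.4f\n",
              x$scenario_id, x$method, x$subject_id, x$avg_error))
  invisible(x)
}

#' Compare the three control methods over a cohort and scenario set
#'
#' Runs every method x scenario x subject combination (3 x 9 x 25 = 675
#' runs for the default cohort) and tabulates the error to the 0.9
#' target.  Scenario speed sequences are drawn once per scenario id from
#' `seed` and shared across subjects and methods, so the comparison is
#' paired.
#'
#' @param cohort list of `virtual_subject`s.
#' @param scenario_ids scenario numbers to run.
#' @param methods control methods to compare.
#' @param n_sessions sessions per scenario.
#' @param seed integer seed for the scenarios' random segments.
#' @inheritParams run_control
#' @return list of class `method_comparison`: `results` (one row per
#'   run: scenario, method, subject, avg_error), `traces` (one row per
#'   session of every run), `by_method`, `by_method_scenario`
#'   (mean-error summaries) and `n_runs`.
#' @export
compare_methods <- function(cohort, scenario_ids = 1:9,
                            methods = c("adaptive", "fixed", "simple"),
                            n_sessions = 20, seed = 1L,
                            constants = gdcr_constants(),
                            mode = "analytic") {
  set.seed(seed)
  scenarios <- lapply(scenario_ids, build_scenario, n_sessions = n_sessions)
  runs <- list()
  traces <- list()
  for (scenario in scenarios) {
    for (method in methods) {
      for (subject in cohort) {
        res <- run_control(subject, scenario, method,
                           constants = constants, mode = mode)
        runs[[length(runs) + 1L]] <-
          data.frame(scenario = scenario$id, method = method,
                     subject = subject$subject_id,
                     avg_error = res$avg_error)
        tr <- res$trace
        tr$scenario <- scenario$id
        tr$method <- method
        tr$subject <- subject$subject_id
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  results <- do.call(rbind, runs)
  traces <- do.call(rbind, traces)
  by_method <- stats::aggregate(avg_error ~ method, results, mean)
  names(by_method)[2] <- "mean_error"
  by_method$n <- as.vector(table(results$method)[by_method$method])
  by_ms <- stats::aggregate(avg_error ~ method + scenario, results, mean)
  names(by_ms)[3] <- "mean_error"
  structure(list(results = results, traces = traces,
                 by_method = by_method, by_method_scenario = by_ms,
                 n_runs = nrow(results)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d runs (%d scenarios x %d methods x %d subjects)\n",
              x$n_runs, length(unique(x$results$scenario)),
              length(unique(x$results$method)),
              length(unique(x$results$subject))))
  print(x$by_method, row.names = FALSE)
  invisible(x)
}

#' Write comparison results to CSV
#'
#' Per-session trace CSV (`scenario,method,subject,session,speed,AT,gdcr,error`)
#' and per-method summary CSV (`method,scenario,mean_error,n`).
#'
#' @param comparison a `method_comparison`.
#' @param trace_path,summary_path output file paths (`NULL` skips one).
#' @export
write_comparison <- function(comparison, trace_path = NULL,
                             summary_path = NULL) {
  stopifnot(inherits(comparison, "method_comparison"))
  if (!is.null(trace_path)) {
    cols <- c("scenario", "method", "subject", "session", "speed",
              "AT", "gdcr", "error")
    utils::write.csv(comparison$traces[cols], trace_path,
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) {
    s <- comparison$by_method_scenario
    s$n <- ave(s$mean_error, s$method, FUN = length)
    utils::write.csv(s[c("method", "scenario", "mean_error", "n")],
                     summary_path, row.names = FALSE, quote = FALSE)
  }
  invisible(comparison)
}

#' Nonparametric rank statistics for GDCR analyses
#'
#' Thin wrappers with the conventions used throughout: Spearman rank
#' correlation with average ranks for ties, two-sided Mann-Whitney U
#' (two groups), Kruskal-Wallis H (k groups) and a Kolmogorov-Smirnov
#' normality check against the sample's own mean and SD.
#'
#' @param x,y paired numeric vectors (for the correlation) .
#' @return `spearman_rho()` returns the correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @param values numeric observations.
#' @param groups group labels, same length as `values`; every group
#'   needs at least two observations.
#' @return `rank_location_test()` returns the `htest` from
#'   [stats::wilcox.test()] (two groups) or [stats::kruskal.test()]
#'   (more).
#' @export
rank_location_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least two observations")
  }
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (nlevels(groups) == 2L) {
    stats::wilcox.test(values ~ groups, exact = FALSE, correct = FALSE)
  } else {
    stats::kruskal.test(values, groups)
  }
}

#' @rdname spearman_rho
#' @return `normality_check()` returns the Kolmogorov-Smirnov `htest`.
#' @export
normality_check <- function(values) {
  stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
}
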