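# Flat key=value run configuration.  The known keys cover the
# thresholds, controller constants, generator and scenario parameters,
# the seed and the output directory; unknown keys are rejected rather
# than silently carried along.

RUN_CONFIG_DEFAULTS <- list(
  AT = 6000, GT = 15000,
  min_duration = 2L, merge_gap = 5L,
  init_multiplier = 1.11, base_gdcr = 0.720,
  target_cap = 0.9, target_backoff = 0.01,
  init_AT = 6000, init_speed = 2.0,
  n_subjects = 25L, amplitude_sd = 0.05, midpoint_sd = 400,
  rate_sdlog = 0.1, leg_asymmetry = 0,
  n_sessions = 20L, seed = 1L,
  out_dir = "gdcr-out"
)

#' Read / write a flat run configuration
#'
#' One `key = value` pair per line; `#` starts a comment.  Unknown keys
#' are an error, missing keys fall back to the defaults, and a written
#' configuration reads back identically.
#'
#' @param path file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  config <- RUN_CONFIG_DEFAULTS
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    value <- trimws(kv[2])
    if (!key %in% names(RUN_CONFIG_DEFAULTS)) {
      stop("unknown config key: '", key, "'")
    }
    default <- RUN_CONFIG_DEFAULTS[[key]]
    config[[key]] <- if (is.character(default)) {
      value
    } else if (is.integer(default)) {
      as.integer(value)
    } else {
      as.numeric(value)
    }
  }
  config
}

#' @rdname read_run_config
#' @param config named list of configuration values (defaults filled in
#'   for missing keys; unknown keys rejected).
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop("unknown config key: '", unknown[1], "'")
  }
  full <- utils::modifyList(RUN_CONFIG_DEFAULTS, config)
  writeLines(vapply(names(full), function(k) {
    sprintf("%s = %s", k, format(full[[k]], scientific = FALSE))
  }, character(1)), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a run as JSON
#' so the run can be reproduced exactly.
#'
#' @param config named configuration list.
#' @param path output file.
#' @export
write_run_manifest <- function(config, path) {
  full <- utils::modifyList(RUN_CONFIG_DEFAULTS, config)
  jsonlite::write_json(
    list(package = "gdcr",
         version = as.character(utils::packageVersion("gdcr")),
         config = full),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
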