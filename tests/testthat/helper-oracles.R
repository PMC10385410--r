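# Independent oracles and fixture builders used across the suite.

# Build a session from explicit channel vectors (defaults quiet).
make_session <- function(gz, ax = NULL, ay = NULL, n = length(gz)) {
  if (is.null(ax)) ax <- rep(0, n)
  if (is.null(ay)) ay <- rep(16384, n)
  imu_session(data.frame(t = (seq_len(n) - 1) / 30,
                         ax = ax, ay = ay, az = rep(0, n),
                         gx = rep(0, n), gy = rep(0, n), gz = gz))
}

# Flat calibration profile matching make_session's baseline.
flat_profile <- function() calibration_profile(0, 16384, 0)

# Brute-force scan of the detection rule, written independently of the
# rle-based implementation: walk the signal sample by sample, close a
# run on a sub-threshold gap of at least `merge_gap`, then drop short
# runs.
oracle_detect <- function(gz, GT, min_duration = 2L, merge_gap = 5L) {
  starts <- integer(0); ends <- integer(0)
  cur_start <- NA_integer_; last_above <- NA_integer_
  for (i in seq_along(gz)) {
    if (gz[i] > GT) {
      if (is.na(cur_start)) {
        cur_start <- i
      } else if (i - last_above > 1L && i - last_above - 1L >= merge_gap) {
        starts <- c(starts, cur_start); ends <- c(ends, last_above)
        cur_start <- i
      }
      last_above <- i
    }
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start); ends <- c(ends, last_above)
  }
  keep <- (ends - starts + 1L) >= min_duration
  data.frame(start_index = starts[keep], end_index = ends[keep])
}

# Rank-then-Pearson Spearman oracle (average ranks for ties).
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Streaming (one-pass Welford-style) mean oracle.
oracle_streaming_mean <- function(x) {
  m <- 0
  for (i in seq_along(x)) m <- m + (x[i] - m) / i
  m
}

# Random walking-ish test signal: sparse supra-threshold gyro pulses
# over noise, paired with random sagittal accel bursts.
random_session <- function(n = 300, n_pulses = 5, GT = 15000) {
  gz <- round(rnorm(n, 0, 2000))
  ax <- round(rnorm(n, 0, 100))
  starts <- sort(sample(seq(5, n - 12), n_pulses))
  starts <- starts[c(TRUE, diff(starts) > 15)]
  for (s in starts) {
    len <- sample(3:8, 1)
    gz[s:(s + len - 1)] <- round(runif(1, GT + 1000, GT + 8000))
    ax[s:(s + len - 1)] <- round(runif(1, 500, 12000))
  }
  make_session(gz, ax = ax)
}

# A default calibrated cohort, computed once per test run.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sample_cohort(calibrate_generator())
    cache
  }
})

# Subject whose true curve is exactly C * G(AT) at every speed.
population_subject <- function(C = 0.95) {
  params <- cohort_params(amplitude_mean = rep(C, 5),
                          amplitude_sd = 0,
                          midpoint_mean = rep(1000 + 7.009 / 0.0009, 5),
                          midpoint_sd = 0, rate_sdlog = 0)
  sample_subject(params, id = sprintf("POP%.2f", C))
}
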