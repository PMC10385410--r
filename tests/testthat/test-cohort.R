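test_that("generator calibration hits the per-speed grid means", {
  params <- calibrate_generator()
  expect_s3_class(params, "cohort_params")
  expect_true(all(abs(attr(params, "calibration_residual")) <= 0.02))
  expect_true(all(params$midpoint_mean > 1000 &
                    params$midpoint_mean < 15000))

  # single-subject, zero-spread cohort: grid mean equals the closed-form
  # mean of the scaled logistic (quadrature oracle)
  p1 <- cohort_params(n_subjects = 1, amplitude_sd = 0, midpoint_sd = 0,
                      rate_sdlog = 0, midpoint_mean = rep(9000, 5))
  s1 <- sample_cohort(p1)[[1]]
  grid <- at_domain_grid()
  got <- mean(subject_gdcr(s1, grid, 2.0))
  want <- s1$amplitude[3] * mean(plogis(s1$rate * (9000 - grid)))
  expect_equal(got, want)

  # an impossible target errors with a diagnostic
  expect_error(
    calibrate_generator(target_means = c(0.9, 0.91, 0.92, 0.93, 0.94)),
    "unattainable")
})

test_that("cohort draws are deterministic and respect the invariants", {
  params <- calibrate_generator()
  a <- sample_cohort(params)
  b <- sample_cohort(params)
  expect_equal(a, b)  # same seed, same cohort
  expect_length(a, 25L)

  other <- params
  other$seed <- 99L
  expect_false(identical(sample_cohort(other), a))

  for (s in a) {
    expect_true(all(s$amplitude >= 0 & s$amplitude <= 1))
    expect_true(!is.unsorted(s$amplitude))  # stronger signal when faster
    expect_true(all(s$midpoint > 1000 & s$midpoint < 15000))
    expect_gt(s$rate, 0)
  }

  # amplitude ordering across many independent draws
  set.seed(31)
  for (i in 1:1000) {
    s <- sample_subject(params)
    expect_true(!is.unsorted(s$amplitude))
  }

  # zero spreads collapse every subject onto the distribution means
  degen <- cohort_params(n_subjects = 4, amplitude_sd = 0, midpoint_sd = 0,
                         rate_sdlog = 0, midpoint_mean = rep(8000, 5))
  dc <- sample_cohort(degen)
  expect_equal(dc[[1]]$amplitude, dc[[3]]$amplitude)
  expect_equal(dc[[2]]$midpoint, rep(8000, 5))
  expect_equal(dc[[4]]$rate, 0.0009)
})

test_that("subject curves interpolate across speed and decrease in AT", {
  params <- calibrate_generator()
  s <- sample_cohort(params)[[3]]
  grid <- seq(1000, 15000, by = 100)

  # node speed: no interpolation
  direct <- s$amplitude[3] * plogis(s$rate * (s$midpoint[3] - grid))
  expect_equal(subject_gdcr(s, grid, 2.0), direct)

  # halfway between nodes: mean of the two node curves
  c10 <- subject_gdcr(s, grid, 1.0)
  c15 <- subject_gdcr(s, grid, 1.5)
  expect_equal(subject_gdcr(s, grid, 1.25), (c10 + c15) / 2)

  # strictly decreasing in AT; near the ceiling at the easiest AT
  v <- subject_gdcr(s, grid, 2.2)
  expect_true(all(diff(v) < 0))
  expect_equal(subject_gdcr(s, 1000, 2.0), s$amplitude[3],
               tolerance = 0.01)

  expect_warning(v_lo <- subject_gdcr(s, 6000, 0.5), "clamped")
  expect_equal(v_lo, subject_gdcr(s, 6000, 1.0))
})

test_that("cohort mean GDCR increases with walking speed", {
  params <- calibrate_generator()
  cohort <- sample_cohort(params)
  grid <- at_domain_grid()
  means <- vapply(params$speeds, function(sp) {
    mean(vapply(cohort, function(s) mean(subject_gdcr(s, grid, sp)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(abs(means - c(0.27, 0.45, 0.49, 0.52, 0.59)) <= 0.02))
})

test_that("synthesized sessions carry the protocol structure", {
  subj <- default_cohort()[[5]]
  set.seed(33)
  session <- synthesize_imu_session(subj, 2.0)
  expect_s3_class(session, "imu_session")
  expect_equal(nrow(session), 1800L)  # 30 Hz x 60 s
  expect_equal(max(session$t), 1799 / 30)

  ranges <- detect_gait_ranges(session, threshold_config(GT = 15000))
  expect_equal(nrow(ranges), 45L)  # 45 swings per minute on one leg

  short <- synthesize_imu_session(subj, 1.5, duration_s = 20)
  expect_equal(nrow(short), 600L)
  expect_equal(nrow(detect_gait_ranges(short, threshold_config())), 15L)

  # standing recording: gravity on y, quiet gyro
  set.seed(34)
  standing <- synthesize_standing()
  expect_equal(nrow(standing), 900L)
  prof <- calibrate_baseline(standing)
  expect_equal(prof$baseline_ay, 16384, tolerance = 10)
  expect_equal(prof$baseline_ax, 0, tolerance = 10)
  expect_equal(nrow(detect_gait_ranges(standing, threshold_config())), 0L)
})

test_that("empirical GDCR from synthesized sessions tracks the curve", {
  subj <- default_cohort()[[5]]
  set.seed(35)
  prof <- calibrate_baseline(synthesize_standing())
  # average four sessions to beat the 45-swing binomial granularity
  emp <- replicate(4, {
    session <- synthesize_imu_session(subj, 2.0)
    cfg <- threshold_config(AT = 6000, GT = 15000)
    ranges <- classify_ranges(detect_gait_ranges(session, cfg),
                              session, prof, cfg)
    compute_gdcr(ranges)$gdcr
  })
  expect_lt(abs(mean(emp) - subject_gdcr(subj, 6000, 2.0)), 0.05)

  # and across the AT grid the whole empirical curve stays within
  # binomial sampling error of the analytic one
  set.seed(36)
  session <- synthesize_imu_session(subj, 2.5)
  curve <- gdcr_curve(session, prof, sweep = "AT",
                      grid = seq(1000, 15000, 500), speed = 2.5)
  analytic <- subject_gdcr(subj, curve$grid, 2.5)
  se <- sqrt(analytic * (1 - analytic) / 45)
  expect_true(all(abs(curve$value - analytic) <= pmax(3.5 * se, 3 / 45)))
})

test_that("cohort session fixtures round-trip through the manifest", {
  params <- calibrate_generator(params = cohort_params(n_subjects = 2))
  cohort <- sample_cohort(params)
  dir <- withr::local_tempdir()
  manifest <- write_cohort_sessions(cohort, dir, speeds = c(1.0, 3.0),
                                    duration_s = 10, seed = 5L)
  expect_equal(nrow(manifest), 4L)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_imu_csv(file.path(dir, manifest$file[1]))
  expect_equal(nrow(back), 300L)
})
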