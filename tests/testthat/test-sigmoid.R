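test_that("candidate sigmoids hit their closed-form anchor values", {
  for (nm in sigmoid_candidates()$name) {
    expect_equal(candidate_value(nm, 0), 0.5, info = nm)
  }
  expect_equal(candidate_value("logistic", 7), 1 / (1 + exp(-7)),
               tolerance = 1e-12)
  expect_equal(candidate_value("logistic", 7), 0.999089, tolerance = 1e-6)
  expect_equal(candidate_value("algebraic", -16.5),
               0.5 + 16.5 / (2 * sqrt(1 + 16.5^2)), tolerance = 1e-12)
  expect_equal(candidate_value("algebraic", -16.5), 0.99908,
               tolerance = 1e-5)
  # each candidate approaches 1 and 0 at its domain ends, the sanity
  # check that the resolved functional forms match their domains
  cand <- sigmoid_candidates()
  for (i in seq_len(nrow(cand))) {
    lo <- candidate_value(cand$name[i], cand$domain_lo[i])
    hi <- candidate_value(cand$name[i], cand$domain_hi[i])
    high_end <- if (cand$increasing[i]) hi else lo
    low_end <- if (cand$increasing[i]) lo else hi
    expect_gt(high_end, 0.96)
    expect_lt(low_end, 0.04)
  }
  expect_warning(candidate_value("error", 3), "outside")
  expect_error(candidate_value("gompertz", 0), "unknown")
})

test_that("AT-domain maps orient every candidate to decrease with AT", {
  expect_equal(map_at_to_domain("logistic", 1000), 7.009)
  expect_equal(map_at_to_domain("logistic", 15000), -5.591)
  expect_equal(map_at_to_domain("error", c(1000, 15000)), c(2, -2.5))
  expect_equal(map_at_to_domain("algebraic", c(1000, 15000)), c(-16.5, 13))
  expect_equal(map_at_to_domain("arctangent", c(1000, 15000)), c(-7, 5.6))
  grid <- at_domain_grid()
  for (nm in sigmoid_candidates()$name) {
    v <- suppressWarnings(candidate_value(nm, map_at_to_domain(nm, grid)))
    expect_true(all(diff(v) < 0), info = nm)
    expect_true(all(v > 0 & v < 1), info = nm)
  }
})

test_that("FG normalization anchors the curve at 1 for AT = 1000", {
  grid <- at_domain_grid()
  raw <- 0.72 * logistic_gdcr(grid)
  curve <- gdcr:::new_gdcr_curve(grid, raw, "AT", 15000, NA_real_)
  fg <- build_fg(curve)
  expect_equal(fg$fg_values[1], 1)
  expect_equal(fg$scale_factor, 1 / raw[1])
  expect_equal(fg$scale_factor, 1.39, tolerance = 0.01)
  expect_equal(max(fg$fg_values), fg$fg_values[1])  # non-increasing input

  unit <- gdcr:::new_gdcr_curve(grid, logistic_gdcr(grid) /
                                  logistic_gdcr(1000), "AT", 15000, NA_real_)
  expect_equal(build_fg(unit)$fg_values, unit$value)  # already normalized

  zero <- gdcr:::new_gdcr_curve(grid, rep(0, length(grid)), "AT", 15000,
                                NA_real_)
  expect_error(build_fg(zero), "positive")

  # grids reaching 20,000 are trimmed to the algorithmic domain
  wide <- gdcr:::new_gdcr_curve(at_grid(), runif(1901), "AT", 15000,
                                NA_real_)
  expect_length(build_fg(wide)$at_grid, 1401L)
})

test_that("average error divides by the step count, not the point count", {
  grid <- at_domain_grid()
  self <- candidate_value("logistic", map_at_to_domain("logistic", grid))
  fg_self <- structure(list(at_grid = grid, fg_values = self,
                            scale_factor = 1), class = "fitted_curve")
  expect_equal(average_error(fg_self, "logistic"), 0)

  # shift the curve by a constant: the sum is 1401 * d, the divisor must
  # be 1400, so the average error is d * 1401/1400
  d <- 0.014
  fg_off <- structure(list(at_grid = grid, fg_values = self + d,
                           scale_factor = 1), class = "fitted_curve")
  expect_equal(average_error(fg_off, "logistic"), d * 1401 / 1400)
  expect_equal(average_error(fg_off, "logistic", kind = "signed"),
               d * 1401 / 1400)

  # random curve against an independent loop-summation oracle
  set.seed(21)
  fg_rand <- structure(list(at_grid = grid,
                            fg_values = sort(runif(length(grid)),
                                             decreasing = TRUE),
                            scale_factor = 1), class = "fitted_curve")
  acc <- 0
  for (i in seq_along(grid)) {
    acc <- acc + abs(fg_rand$fg_values[i] - self[i])
  }
  expect_equal(average_error(fg_rand, "logistic"), acc / 1400)

  short <- structure(list(at_grid = 1000, fg_values = 1, scale_factor = 1),
                     class = "fitted_curve")
  expect_error(average_error(short, "logistic"), "two grid points")
})

test_that("selection recovers the generating family for all candidates", {
  grid <- at_domain_grid()
  for (nm in sigmoid_candidates()$name) {
    v <- suppressWarnings(candidate_value(nm, map_at_to_domain(nm, grid)))
    fg <- structure(list(at_grid = grid, fg_values = v, scale_factor = 1),
                    class = "fitted_curve")
    ranking <- suppressWarnings(select_best(fg))
    expect_identical(ranking$candidate[1], nm)
    expect_equal(ranking$avg_error[1], 0, tolerance = 1e-12)
    expect_equal(ranking$rank, 1:4)
    expect_true(all(diff(ranking$avg_error) >= 0))
  }
})

test_that("the calibrated logistic G obeys its closed form and symmetry", {
  expect_equal(logistic_gdcr(1000), 1 / (1 + exp(-7.009)))
  expect_equal(logistic_gdcr(1000), 0.99910, tolerance = 1e-5)
  expect_equal(logistic_gdcr(15000), 1 / (1 + exp(5.591)))
  expect_equal(logistic_gdcr(15000), 0.00372, tolerance = 1e-3)
  m <- 1000 + 7.009 / 0.0009
  expect_equal(logistic_gdcr(m), 0.5)
  expect_equal(m, 8787.78, tolerance = 0.01)
  # logistic symmetry about the midpoint
  d <- seq(100, 6000, by = 100)
  expect_equal(logistic_gdcr(m - d) + logistic_gdcr(m + d),
               rep(1, length(d)))
  grid <- at_domain_grid()
  expect_true(all(diff(logistic_gdcr(grid)) < 0))
})
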