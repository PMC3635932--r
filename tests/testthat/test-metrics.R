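test_that("estimation error is half the median CI width over the denominator", {
  sp <- spec_benchmark()
  # widths 4, 6, 8 about estimates 20 -> median half-width 3, denominators 20
  fits <- make_fit_frame(rate = c(20, 20, 20),
                         lower = c(18, 17, 16), upper = c(22, 23, 24),
                         p_change = rep(0.5, 3))
  expect_equal(estimation_error(fits, sp), 100 * 3 / 20)
  expect_equal(estimation_error(fits, sp, denominator = "median_estimate"),
               100 * 3 / 20)
  # a biased estimator separates the two conventions
  fits$rate_visit1 <- c(26, 26, 26)
  expect_equal(estimation_error(fits, sp, denominator = "median_estimate"),
               100 * 3 / 26)
  # degenerate zero-width intervals give zero error
  fits0 <- make_fit_frame(20, 20, 20, 0.5)
  expect_identical(estimation_error(fits0, sp), 0)
})

test_that("estimation error is suppressed at >= 10% failed fits", {
  sp <- spec_benchmark()
  fits <- make_fit_frame(rate = rep(20, 10), lower = rep(18, 10),
                         upper = rep(22, 10), p_change = rep(0.5, 10),
                         failed = c(rep(FALSE, 9), TRUE))
  expect_true(is.na(estimation_error(fits, sp)))
  fits$failed[10] <- FALSE
  expect_false(is.na(estimation_error(fits, sp)))
  expect_error(estimation_error(fits[0, ], sp), "no replicate fits")
})

test_that("power counts failures as non-significant over all replicates", {
  fits <- make_fit_frame(rate = rep(20, 4), lower = rep(18, 4),
                         upper = rep(22, 4),
                         p_change = c(0.049, 0.051, 0.001, 0.001),
                         failed = c(FALSE, FALSE, FALSE, TRUE))
  # two significant of four (the failed replicate has p < 0.05 but cannot count)
  expect_equal(detection_power(fits), 50)
  fits$failed <- TRUE
  expect_identical(detection_power(fits), 0)
})

test_that("bias and coverage follow their definitions", {
  sp <- spec_benchmark()  # true rate 20
  fits <- make_fit_frame(rate = c(24, 26, 28), lower = c(1, 1, 30),
                         upper = c(25, 27, 40), p_change = rep(0.5, 3))
  expect_equal(rate_bias(fits, sp), 100 * (26 - 20) / 20)
  # two of three intervals contain 20
  expect_equal(ci_coverage(fits, sp), 100 * 2 / 3)
  # an interval of (0, Inf) always covers
  fits_all <- make_fit_frame(rate = rep(26, 3), lower = 0, upper = Inf,
                             p_change = rep(0.5, 3))
  expect_identical(ci_coverage(fits_all, sp), 100)
  # every fit failed: bias and coverage are unavailable
  fits$failed <- TRUE
  expect_true(is.na(rate_bias(fits, sp)))
  expect_true(is.na(ci_coverage(fits, sp)))
})

test_that("scenario summaries assemble all metrics deterministically", {
  sp <- spec_benchmark()
  fits <- make_fit_frame(rate = c(19, 20, 21, 22),
                         lower = c(15, 16, 17, 18),
                         upper = c(23, 24, 25, 26),
                         p_change = c(0.01, 0.2, 0.6, 0.03))
  s1 <- summarize_scenario(fits, sp)
  s2 <- summarize_scenario(fits, sp)
  expect_identical(s1, s2)
  expect_identical(s1$replicates, 4L)
  expect_equal(s1$power_pct, 50)
  # median of an even number of replicates uses the midpoint
  expect_equal(s1$median_rate_estimate, 20.5)
  expect_equal(s1$expected_incidents_visit1, 100)
  expect_equal(s1$expected_incidents_total, 200)
  expect_error(summarize_scenario(fits[0, ], sp), "no replicate fits")
  expect_error(summarize_scenario(list(), sp))
})

test_that("metrics accept a list of single fits as well as a fit frame", {
  f1 <- fit_rate_model(data.frame(visit = c(0, 1),
                                  exposure_years = c(500, 500),
                                  count = c(100, 50)))
  f2 <- fit_rate_model(data.frame(visit = c(0, 1),
                                  exposure_years = c(500, 500),
                                  count = c(90, 85)))
  sp <- spec_benchmark()
  expect_equal(detection_power(list(f1, f2)), 50)
  expect_type(estimation_error(list(f1, f2), sp), "double")
})
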