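# Luminescence/absorbance calibration: forward, inverse, concentration
# transforms and OLS standard-curve fitting.

paper_cal <- probe_calibration()

test_that("forward prediction follows the probe line", {
  expect_equal(predict_log_intensity(paper_cal, 0), 2.126)
  expect_equal(predict_log_intensity(paper_cal, 50), 3.008)
  expect_equal(predict_log_intensity(paper_cal, 100), 3.890)
  expect_error(predict_log_intensity(paper_cal, 120), "percent")
  frac <- linear_calibration(1.764, 2.126, "fraction")
  expect_error(predict_log_intensity(frac, 1.2), "fraction")
})

test_that("inverse prediction undoes the forward map and clips out-of-range readouts", {
  expect_equal(as.numeric(invert_to_ratio(paper_cal, 2.126)), 0)
  expect_equal(as.numeric(invert_to_ratio(paper_cal, 3.008)), 50)
  expect_equal(as.numeric(invert_to_ratio(paper_cal, predict_log_intensity(paper_cal, 37.2))), 37.2)

  expect_warning(out <- invert_to_ratio(paper_cal, 4.2), "clipped")
  expect_equal(as.numeric(out), 100)
  expect_true(attr(out, "clipped"))

  expect_error(invert_to_ratio(linear_calibration(0, 1), 2), "not invertible")
})

test_that("forward/inverse composition is the identity over random calibrations", {
  set.seed(42)
  for (i in 1:50) {
    cal <- rand_calibration()
    hi <- if (cal$convention == "percent") 100 else 1
    ratio <- runif(5, 0, hi)
    back <- as.numeric(invert_to_ratio(cal, predict_log_intensity(cal, ratio)))
    expect_equal(back, ratio, tolerance = 1e-9)
  }
})

test_that("raw intensity converts to the Fe redox couple", {
  expect_equal(fe2_from_intensity(paper_cal, 10^2.126, 2)$fe2_mM, 0)
  # the top of the calibrated range: float round-off may clip, value is exact
  expect_equal(suppressWarnings(fe2_from_intensity(paper_cal, 10^3.890, 2)$fe2_mM), 2)
  out <- fe2_from_intensity(paper_cal, 10^3.008, 2)
  expect_equal(out$fe2_mM, 1)
  expect_equal(out$fe2_mM + out$fe3_mM, 2)
  expect_error(fe2_from_intensity(paper_cal, -5, 2), "positive")
  expect_error(fe2_from_intensity(paper_cal, 0, 2), "positive")
})

test_that("fe2_from_intensity is monotone in intensity for positive slope", {
  set.seed(7)
  intens <- sort(10^runif(20, 2.126, 3.89))
  fe2 <- fe2_from_intensity(paper_cal, intens, 2)$fe2_mM
  expect_true(all(diff(fe2) >= 0))
})

test_that("OLS fitting recovers a noise-free line exactly", {
  ratios <- c(0, 25, 50, 75, 100)
  y <- predict_log_intensity(paper_cal, ratios)
  cal <- fit_linear_calibration(ratios, y)
  expect_equal(cal$slope, 0.01764, tolerance = 1e-9)
  expect_equal(cal$intercept, 2.126, tolerance = 1e-9)
  expect_lt(attr(cal, "rss"), 1e-18)
  expect_equal(attr(cal, "r"), 1, tolerance = 1e-9)

  # two points: exact interpolation
  two <- fit_linear_calibration(c(10, 30), c(1, 2))
  expect_equal(two$slope * c(10, 30) + two$intercept, c(1, 2), tolerance = 1e-12)

  # constant response: flat line
  flat <- fit_linear_calibration(c(0, 1, 2), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 1)
})

test_that("OLS fit matches the closed-form oracle on random lines", {
  set.seed(11)
  for (i in 1:25) {
    x <- runif(8, 0, 100)
    y <- runif(1, -1, 1) * x + runif(1, -2, 4)
    cal <- fit_linear_calibration(x, y)
    oracle <- ols_oracle(x, y)
    expect_equal(cal$slope, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(cal$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
  }
})

test_that("degenerate calibration designs are rejected", {
  expect_error(fit_linear_calibration(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_error(fit_linear_calibration(1, 2), "nsufficient")
  expect_error(fit_linear_calibration(c(0, 50), c(100, -3), log10_response = TRUE),
               "positive")
})

test_that("raw-intensity fitting logs before regressing", {
  ratios <- seq(0, 100, by = 20)
  intens <- 10^predict_log_intensity(paper_cal, ratios)
  cal <- fit_linear_calibration(ratios, intens, log10_response = TRUE)
  expect_equal(cal$slope, 0.01764, tolerance = 1e-9)
  expect_equal(cal$intercept, 2.126, tolerance = 1e-9)
})
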