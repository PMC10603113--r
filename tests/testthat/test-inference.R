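# Model fitting, agreement metrics and derived quantities.

test_that("fitting noise-free data initialized at truth stays at truth", {
  truth <- default_truth()
  obs <- generate_coculture_series(truth, noise = zero_noise())
  fit <- fit_lan_model(obs, truth, free = c("E_S", "E_R"))
  expect_lt(fit$rss, 1e-10)
  expect_equal(lan_to_symbols(fit$estimate), lan_to_symbols(truth), tolerance = 1e-6)
})

test_that("perturbed initializations recover free parameters from noise-free data", {
  truth <- default_truth()
  obs <- generate_coculture_series(truth, noise = zero_noise())
  syms <- lan_to_symbols(truth)
  init <- syms
  init[c("E_S", "E_R")] <- init[c("E_S", "E_R")] * c(1.2, 0.8)
  fit <- fit_lan_model(obs, lan_from_symbols(init), free = c("E_S", "E_R"))
  est <- lan_to_symbols(fit$estimate)
  expect_equal(est[c("E_S", "E_R")], syms[c("E_S", "E_R")], tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("the fit never ends worse than its initialization", {
  truth <- default_truth()
  obs <- generate_coculture_series(truth, noise = noise_spec(seed = 9))
  # shrink the growth amplitudes: a safely integrable but clearly wrong start
  init_syms <- lan_to_symbols(truth)
  init_syms[c("E_S", "E_R")] <- init_syms[c("E_S", "E_R")] * c(0.85, 0.9)
  init <- lan_from_symbols(init_syms)
  # standardized RSS at the initialization point
  traj0 <- suppressWarnings(simulate_lan(init, times = obs$time_h))
  rss0 <- sum(vapply(c("fe2_mM", "cells_S_od", "cells_R_od"), function(ch)
    sum(((obs[[ch]] - traj0[[ch]]) / diff(range(obs[[ch]])))^2), numeric(1L)))
  fit <- fit_lan_model(obs, init, free = c("E_S", "E_R"))
  expect_lte(fit$rss, rss0)
})

test_that("malformed observation tables are rejected", {
  obs <- generate_coculture_series(noise = noise_spec(seed = 2))
  expect_error(fit_lan_model(obs[, "fe2_mM", drop = FALSE], default_truth()), "time_h")
  expect_error(fit_lan_model(obs[1:4, ], default_truth()), "at least 6")
  broken <- structure(list(time_h = obs$time_h, fe2_mM = obs$fe2_mM[1:5]),
                      class = "data.frame", row.names = seq_along(obs$time_h))
  expect_error(fit_lan_model(broken, default_truth()), "length")
  expect_error(fit_lan_model(obs, default_truth(), free = "Z_S"), "unknown free")
})

test_that("pearson_r matches the direct formula and handles edge cases", {
  expect_equal(pearson_r(1:3, 1:3), 1)
  expect_equal(pearson_r(1:3, -(1:3)), -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "same length")
})

test_that("pearson_r is invariant under positive affine transforms", {
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    expect_equal(pearson_r(a * x + b, y), pearson_r(x, y), tolerance = 1e-12)
  }
})

test_that("the t-transform p-value agrees with cor.test", {
  set.seed(13)
  x <- rnorm(9); y <- x + rnorm(9, sd = 0.8)
  got <- pearson_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("peaks are located with the documented tie-break and boundary flag", {
  pk <- find_peak(c(0, 12, 24, 36), c(0, 0.5, 0.76, 0.6))
  expect_equal(pk$t_peak, 24)
  expect_equal(pk$peak, 0.76)
  expect_true(pk$interior)

  rising <- find_peak(0:5, c(0, 1, 2, 3, 4, 5))
  expect_false(rising$interior)

  tie <- find_peak(c(0, 12, 24, 36), c(0, 0.7, 0.7, 0.1))
  expect_equal(tie$t_peak, 12)
})

test_that("derived metrics follow their formulas", {
  expect_identical(od_to_cells(1), 1e9)
  expect_identical(od_to_cells(0), 0)
  expect_identical(od_to_cells(0.5), 5e8)
  expect_error(od_to_cells(-0.1), ">= 0")

  expect_equal(relative_abundance(1, 1), c(fraction_S = 0.5, fraction_R = 0.5))
  expect_equal(relative_abundance(0, 2), c(fraction_S = 0, fraction_R = 1))
  expect_equal(relative_abundance(0.3, 0.9), c(fraction_S = 0.25, fraction_R = 0.75))
  expect_error(relative_abundance(0, 0), "undefined")

  expect_equal(co2_fixation_rate(10, 96, 0.5), 10 / 96 / 0.5)
  expect_equal(co2_fixation_rate(0, 96, 1), 0)
  expect_equal(co2_fixation_rate(30, 96, 1), 0.3125)
  expect_error(co2_fixation_rate(10, 0, 1), "interval")
  expect_error(co2_fixation_rate(10, 96, 0), "weight")
})

test_that("zero-noise recovery is exact with perfect agreement", {
  rep0 <- recovery_experiment(noise = zero_noise(), seeds = 1L)
  expect_true(all(abs(rep0$summary$rel_bias) < 1e-3))
  expect_true(all(abs(rep0$median_r - 1) < 1e-6))
})

test_that("doubling the noise does not improve the Fe2+ agreement", {
  ns2 <- noise_spec(od_sd = 0.04, fe2_sd = 0.16, lum_cv = 0.1, abs_sd = 0.02)
  r1 <- recovery_experiment(seeds = 1:8)
  r2 <- recovery_experiment(noise = ns2, seeds = 1:8)
  expect_lte(r2$median_r[["fe2_mM"]], r1$median_r[["fe2_mM"]])
})
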