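# Co-culture ODE model: rate blocks, right-hand side, simulation.

test_that("rate blocks validate their parameter domain", {
  expect_error(rate_block(-1, 1, 1, 10, 2), "amplitude")
  expect_error(rate_block(1, 0, 1, 10, 2), "denominator")
  expect_error(rate_block(1, 1, -2, 10, 2), "denominator")
  expect_error(rate_block(1, 1, 1, 0, 2), "half_time")
  expect_error(rate_block(1, 1, 1, 10, 0), "exponent")
})

test_that("rate coefficients interpolate between their asymptotes", {
  const <- rate_block(3, 1.5, 1.5, 20, 2)
  expect_equal(rate_coefficient(const, c(0, 7, 100)), rep(2, 3))

  blk <- rate_block(1.2, 0.5, 4, 24, 3)
  expect_equal(rate_coefficient(blk, 0), 1.2 / 0.5)
  expect_equal(rate_coefficient(blk, 1e6 * 24), 1.2 / 4, tolerance = 1e-6)
  # strictly positive and continuous on a fine grid
  y <- rate_coefficient(blk, seq(0, 200, by = 0.1))
  expect_true(all(y > 0))
  expect_lt(max(abs(diff(y))), 0.05)
})

test_that("the right-hand side honours its multiplicative structure", {
  p <- default_truth()
  expect_equal(unname(lan_rhs(c(0, 0, 1), 10, p)), c(0, 0, 0))
  d <- lan_rhs(c(0.5, 0.5, 0), 10, p)
  expect_equal(unname(d[["cells_S"]]), 0)          # no Fe2+, router stalls
  d <- lan_rhs(c(0.5, 0.5, p$fe_total), 10, p)
  expect_equal(unname(d[["cells_R"]]), 0)          # no Fe3+, actuator stalls
  expect_error(lan_rhs(c(0.5, NaN, 1), 10, p), "cells_R")
})

test_that("the actuator-driver sensitivity switch swaps the growth factor", {
  p <- default_truth()
  d_fe3 <- lan_rhs(c(0.4, 0.4, 0.5), 24, p, actuator_driver = "fe3")
  d_fe2 <- lan_rhs(c(0.4, 0.4, 0.5), 24, p, actuator_driver = "fe2")
  expect_equal(d_fe2[["cells_R"]] / d_fe3[["cells_R"]], 0.5 / (2 - 0.5))
  expect_equal(d_fe2[["cells_S"]], d_fe3[["cells_S"]])
})

test_that("a frozen redox pool leaves fe2 constant", {
  p <- default_truth()
  p$ferate_S$amplitude <- 0
  p$ferate_R$amplitude <- 0
  p$fe2_0 <- 0.05
  traj <- simulate_lan(p, times = seq(0, 96, by = 8))
  expect_equal(traj$fe2_mM, rep(0.05, nrow(traj)), tolerance = 1e-9)
})

test_that("the packaged dynamics rise to an interior Fe2+ peak then decline", {
  traj <- simulate_lan(default_truth(), times = seq(0, 96, by = 0.5))
  pk <- find_peak(traj$time_h, traj$fe2_mM)
  expect_true(pk$interior)
  expect_equal(traj$fe2_mM[1], 0)
  i <- which.max(traj$fe2_mM)
  expect_true(all(diff(traj$fe2_mM[1:i]) >= -1e-9))          # rise
  expect_true(all(diff(traj$fe2_mM[i:nrow(traj)]) <= 1e-9))  # fall
  expect_lt(traj$fe2_mM[nrow(traj)], pk$peak)
})

test_that("densities stay non-negative and grow monotonically while Fe2+ is in range", {
  set.seed(59)
  for (p in list(default_truth(), jitter_truth(), jitter_truth())) {
    traj <- suppressWarnings(simulate_lan(p, times = seq(0, 96, by = 2)))
    expect_true(all(traj$cells_S_od >= 0 & traj$cells_R_od >= 0))
    expect_true(all(traj$fe2_mM >= 0 & traj$fe2_mM <= p$fe_total))
    # growth rates are non-negative only while the pool is in range; stop
    # checking at the first boundary contact after t = 0 (where fe2_0 = 0
    # is a genuine initial condition, not a clamp)
    bad <- which(traj$fe2_mM[-1] <= 0 | traj$fe2_mM[-1] >= p$fe_total) + 1L
    upto <- if (length(bad)) bad[1L] - 1L else nrow(traj)
    expect_gt(upto, 5L)   # the premise must hold on a substantial window
    expect_true(all(diff(traj$cells_S_od[1:upto]) >= -1e-9))
    expect_true(all(diff(traj$cells_R_od[1:upto]) >= -1e-9))
  }
})

test_that("refinement oracle: halving the production tolerances changes nothing", {
  tt <- seq(0, 96, by = 4)
  base <- simulate_lan(default_truth(), times = tt)                 # 1e-8 / 1e-10
  half <- simulate_lan(default_truth(), times = tt, rtol = 5e-9, atol = 5e-11)
  tight <- simulate_lan(default_truth(), times = tt, rtol = 1e-9, atol = 1e-12)
  for (ch in c("cells_S_od", "cells_R_od", "fe2_mM")) {
    expect_lt(max(abs(base[[ch]] - half[[ch]])), 1e-5)
    expect_lt(max(abs(base[[ch]] - tight[[ch]])), 1e-5)
  }
})

test_that("frozen-growth limit matches the closed-form integral", {
  p <- default_truth()
  p$growth_S$amplitude <- 0
  p$growth_R$amplitude <- 0
  p$ferate_R$amplitude <- 0
  tt <- c(0, 12, 24, 48, 96)
  traj <- simulate_lan(p, times = tt)
  for (i in seq_along(tt)[-1]) {
    closed <- p$cells_S0 * integrate(function(s) rate_coefficient(p$ferate_S, s),
                                     0, tt[i], rel.tol = 1e-10)$value
    expect_equal(traj$fe2_mM[i], closed, tolerance = 1e-6)
  }
})

test_that("iron conservation is exact by construction", {
  traj <- simulate_lan(default_truth(), times = seq(0, 96, by = 6))
  expect_identical(conservation_report(traj), 0)

  hand <- data.frame(time_h = 0:3, fe2_mM = c(0, 0.3, 0.6, 0.4),
                     fe3_mM = 2 - c(0, 0.3, 0.6, 0.4))
  expect_identical(conservation_report(hand, 2), 0)
  hand$fe3_mM[2] <- hand$fe3_mM[2] + 0.1
  expect_equal(conservation_report(hand, 2), 0.1)
})

test_that("output grid violations are rejected", {
  expect_error(simulate_lan(default_truth(), times = c(0, 5, 5, 10)), "strictly increasing")
  expect_error(simulate_lan(default_truth(), times = c(-1, 5)), ">= 0")
})

test_that("symbol flattening round-trips the parameter object", {
  p <- default_truth()
  syms <- lan_to_symbols(p)
  expect_length(syms, 24L)
  expect_equal(lan_from_symbols(syms), p)
  expect_error(lan_from_symbols(syms[-1]), "missing parameter symbols")
})
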