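# Coupled co-culture ODE model with an iron redox cycle.
#
# State is (cells_S, cells_R, fe2): router density, actuator density and the
# shared Fe2+ pool. Fe3+ is never integrated; it is derived as
# fe_total - fe2, which enforces the closed two-state redox cycle exactly.
#
#   d cells_S/dt = fe2              * cells_S * g_S(t)
#   d cells_R/dt = (fe_total - fe2) * cells_R * g_R(t)
#   d fe2/dt     = cells_S * q_S(t) - cells_R * q_R(t)
#
# where each time-varying per-cell coefficient g(t), q(t) is a "rate block":
# a constant amplitude divided by a 4PL-shaped denominator.

#' Time-varying rate block
#'
#' The per-cell rate coefficient used throughout the co-culture model:
#' `amplitude / (late_denom + (early_denom - late_denom) / (1 + (t/half_time)^exponent))`.
#' At `t = 0` the coefficient equals `amplitude / early_denom`; as t grows
#' it moves sigmoidally to `amplitude / late_denom`.
#'
#' @param amplitude Numerator constant, >= 0.
#' @param early_denom,late_denom Denominator asymptotes at t = 0 and
#'   t -> infinity; both must be > 0 so the coefficient is defined and
#'   continuous for all t >= 0.
#' @param half_time Denominator half-transition time in hours, > 0.
#' @param exponent Denominator shape exponent, > 0.
#' @return An object of class `rate_block`.
#' @export
rate_block <- function(amplitude, early_denom, late_denom, half_time, exponent) {
  vals <- c(amplitude, early_denom, late_denom, half_time, exponent)
  if (!all(is.finite(vals))) stop("rate block parameters must be finite")
  if (amplitude < 0) stop("rate block amplitude must be >= 0")
  if (early_denom <= 0 || late_denom <= 0)
    stop("rate block denominator asymptotes must be > 0")
  if (half_time <= 0) stop("rate block half_time must be > 0")
  if (exponent <= 0) stop("rate block exponent must be > 0")
  structure(list(amplitude = amplitude, early_denom = early_denom,
                 late_denom = late_denom, half_time = half_time,
                 exponent = exponent),
            class = "rate_block")
}

#' Evaluate a rate block
#'
#' @param block A [rate_block()].
#' @param t Time in hours, >= 0.
#' @return The per-cell rate coefficient at each `t`; continuous and
#'   non-negative, equal to `amplitude/early_denom` at t = 0 and tending to
#'   `amplitude/late_denom`.
#' @export
rate_coefficient <- function(block, t) {
  stopifnot(inherits(block, "rate_block"), is.numeric(t))
  if (any(t < 0)) stop("time must be >= 0")
  block$amplitude /
    (block$late_denom + (block$early_denom - block$late_denom) /
       (1 + (t / block$half_time)^block$exponent))
}

#' Full parameter set of the co-culture model
#'
#' @param growth_S,growth_R Growth [rate_block()]s of the router and
#'   actuator species (symbols E, F, G, H, I per species).
#' @param ferate_S,ferate_R Fe2+ production and consumption
#'   [rate_block()]s (symbols J, K, L, M, N per species).
#' @param fe_total Total iron pool in mM (default 2, the experimental
#'   initial Fe3+ concentration).
#' @param cells_S0,cells_R0 Initial densities in OD600 units, >= 0.
#' @param fe2_0 Initial Fe2+ in mM, inside `[0, fe_total]` (default 0: all
#'   iron starts as Fe3+).
#' @return An object of class `lan_parameters`.
#' @seealso [default_truth()] for the packaged parameter set,
#'   [simulate_lan()] to integrate the model.
#' @export
lan_parameters <- function(growth_S, growth_R, ferate_S, ferate_R,
                           fe_total = 2, cells_S0 = 0.008, cells_R0 = 0.008,
                           fe2_0 = 0) {
  for (b in list(growth_S, growth_R, ferate_S, ferate_R))
    stopifnot(inherits(b, "rate_block"))
  stopifnot(is.numeric(fe_total), fe_total > 0,
            is.numeric(cells_S0), cells_S0 >= 0,
            is.numeric(cells_R0), cells_R0 >= 0,
            is.numeric(fe2_0), fe2_0 >= 0, fe2_0 <= fe_total)
  structure(list(growth_S = growth_S, growth_R = growth_R,
                 ferate_S = ferate_S, ferate_R = ferate_R,
                 fe_total = fe_total, cells_S0 = cells_S0,
                 cells_R0 = cells_R0, fe2_0 = fe2_0),
            class = "lan_parameters")
}

#' @export
print.lan_parameters <- function(x, ...) {
  v <- lan_to_symbols(x)
  cat("Co-culture model parameters:\n")
  cat("  growth_S (E,F,G,H,I):", sprintf("%.4g", v[c("E_S", "F_S", "G_S", "H_S", "I_S")]), "\n")
  cat("  growth_R (E,F,G,H,I):", sprintf("%.4g", v[c("E_R", "F_R", "G_R", "H_R", "I_R")]), "\n")
  cat("  ferate_S (J,K,L,M,N):", sprintf("%.4g", v[c("J_S", "K_S", "L_S", "M_S", "N_S")]), "\n")
  cat("  ferate_R (J,K,L,M,N):", sprintf("%.4g", v[c("J_R", "K_R", "L_R", "M_R", "N_R")]), "\n")
  cat(sprintf("  fe_total = %g mM, cells_S0 = %g OD, cells_R0 = %g OD, fe2_0 = %g mM\n",
              x$fe_total, x$cells_S0, x$cells_R0, x$fe2_0))
  invisible(x)
}

# flat symbol-name representation, mirroring the per-species constants
# (E..I growth, J..N Fe rate) so parameter files can be cross-checked
# against the printed equations
block_symbols <- function(block, letters) {
  setNames(c(block$amplitude, block$late_denom, block$early_denom,
             block$half_time, block$exponent), letters)
}

symbols_block <- function(v, letters) {
  rate_block(amplitude = v[[letters[1L]]], late_denom = v[[letters[2L]]],
             early_denom = v[[letters[3L]]], half_time = v[[letters[4L]]],
             exponent = v[[letters[5L]]])
}

sym_names <- function() {
  c(paste0(c("E", "F", "G", "H", "I"), "_S"), paste0(c("E", "F", "G", "H", "I"), "_R"),
    paste0(c("J", "K", "L", "M", "N"), "_S"), paste0(c("J", "K", "L", "M", "N"), "_R"),
    "fe_total", "cells_S0", "cells_R0", "fe2_0")
}

#' Flatten co-culture parameters to named symbols
#'
#' Converts a [lan_parameters()] object to/from a flat named numeric vector
#' using the per-species symbol names `E_S ... N_R` plus `fe_total`,
#' `cells_S0`, `cells_R0` and `fe2_0`. This is the representation used in
#' plain-text parameter files and in free-parameter masks for fitting.
#'
#' @param params A [lan_parameters()] object.
#' @return `lan_to_symbols`: a named numeric vector of length 24.
#' @export
lan_to_symbols <- function(params) {
  stopifnot(inherits(params, "lan_parameters"))
  c(block_symbols(params$growth_S, paste0(c("E", "F", "G", "H", "I"), "_S")),
    block_symbols(params$growth_R, paste0(c("E", "F", "G", "H", "I"), "_R")),
    block_symbols(params$ferate_S, paste0(c("J", "K", "L", "M", "N"), "_S")),
    block_symbols(params$ferate_R, paste0(c("J", "K", "L", "M", "N"), "_R")),
    fe_total = params$fe_total, cells_S0 = params$cells_S0,
    cells_R0 = params$cells_R0, fe2_0 = params$fe2_0)
}

#' @rdname lan_to_symbols
#' @param symbols A named numeric vector as produced by `lan_to_symbols`.
#' @return `lan_from_symbols`: a [lan_parameters()] object.
#' @export
lan_from_symbols <- function(symbols) {
  missing <- setdiff(sym_names(), names(symbols))
  if (length(missing))
    stop("missing parameter symbols: ", paste(missing, collapse = ", "))
  v <- as.list(symbols)
  lan_parameters(
    growth_S = symbols_block(v, paste0(c("E", "F", "G", "H", "I"), "_S")),
    growth_R = symbols_block(v, paste0(c("E", "F", "G", "H", "I"), "_R")),
    ferate_S = symbols_block(v, paste0(c("J", "K", "L", "M", "N"), "_S")),
    ferate_R = symbols_block(v, paste0(c("J", "K", "L", "M", "N"), "_R")),
    fe_total = v$fe_total, cells_S0 = v$cells_S0,
    cells_R0 = v$cells_R0, fe2_0 = v$fe2_0)
}

#' Right-hand side of the co-culture ODE system
#'
#' Instantaneous derivatives of the state `(cells_S, cells_R, fe2)`:
#' router growth is driven by the Fe2+ it can respire on, actuator growth
#' by the Fe3+ pool `fe_total - fe2`, and the shared Fe2+ pool gains from
#' the router and loses to the actuator in proportion to their densities.
#'
#' As printed in the source equations, actuator growth is driven by the
#' Fe3+ pool `fe_total - fe2` even though the species oxidizes Fe2+; the
#' `actuator_driver = "fe2"` variant swaps that factor for `fe2` and is
#' provided for sensitivity analysis only.
#'
#' @param state Named or positional numeric vector
#'   `(cells_S, cells_R, fe2)`, finite.
#' @param t Time in hours, >= 0.
#' @param params A [lan_parameters()] object.
#' @param actuator_driver `"fe3"` (default, the printed form) or `"fe2"`.
#' @return Named numeric vector of derivatives
#'   `(cells_S, cells_R, fe2)` per hour.
#' @export
lan_rhs <- function(state, t, params, actuator_driver = c("fe3", "fe2")) {
  actuator_driver <- match.arg(actuator_driver)
  stopifnot(inherits(params, "lan_parameters"), length(state) == 3L)
  nm <- c("cells_S", "cells_R", "fe2")
  if (any(!is.finite(state))) {
    bad <- nm[which(!is.finite(state))[1L]]
    stop(sprintf("non-finite state component '%s'", bad))
  }
  S <- state[[1L]]; R <- state[[2L]]; f <- state[[3L]]
  r_driver <- if (actuator_driver == "fe3") params$fe_total - f else f
  setNames(c(f * S * rate_coefficient(params$growth_S, t),
             r_driver * R * rate_coefficient(params$growth_R, t),
             S * rate_coefficient(params$ferate_S, t) -
               R * rate_coefficient(params$ferate_R, t)),
           nm)
}

# Guarded integration core. The printed equations have no saturation: if
# the Fe2+ pool overshoots fe_total the actuator driver goes negative and
# the system can blow up in finite time. Once the state leaves a generous
# trust region the derivatives are zeroed (freezing the state) and the
# escape time recorded, so callers get a finite solution plus a diagnosis
# instead of a solver stall. Parameter estimation relies on this to keep a
# usable descent direction outside the integrable region.
sim_core <- function(params, times, rtol = 1e-8, atol = 1e-10,
                     actuator_driver = "fe3") {
  grid <- if (times[1L] > 0) c(0, times) else times
  y0 <- c(cells_S = params$cells_S0, cells_R = params$cells_R0,
          fe2 = params$fe2_0)
  cap_den <- 1e4
  cap_fe <- 10 * params$fe_total
  t_escape <- NA_real_
  rhs_desolve <- function(t, y, p) {
    if (any(!is.finite(y)) || y[1L] > cap_den || y[2L] > cap_den ||
        y[3L] > cap_fe || y[3L] < -cap_fe) {
      if (is.na(t_escape) || t < t_escape) t_escape <<- t
      return(list(c(0, 0, 0)))
    }
    list(unname(lan_rhs(y, t, p, actuator_driver = actuator_driver)))
  }
  sol <- try(suppressWarnings(
    deSolve::ode(y = y0, times = grid, func = rhs_desolve, parms = params,
                 method = "ode45", rtol = rtol, atol = atol)), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(grid)) {
    if (is.na(t_escape))
      t_escape <- if (inherits(sol, "try-error")) 0 else sol[nrow(sol), 1L]
    return(list(sol = NULL, t_escape = t_escape))
  }
  if (is.na(t_escape) && any(!is.finite(sol)))
    t_escape <- sol[which(!stats::complete.cases(sol))[1L], 1L]
  list(sol = sol[match(times, grid), , drop = FALSE], t_escape = t_escape)
}

#' Simulate the co-culture model
#'
#' Integrates the coupled ODE system with an adaptive explicit Runge--Kutta
#' scheme (Dormand--Prince 4(5), the classic ode45 pairing) and returns the
#' trajectory on the requested output grid. Fe3+ is derived pointwise as
#' `fe_total - fe2`, so iron conservation holds exactly by construction.
#' Solver round-off can leave fe2 marginally outside `[0, fe_total]`; such
#' excursions are clamped in post-processing, the largest clamp magnitude
#' is recorded in the `clamp_mM` attribute, and a warning is raised if it
#' exceeds 1e-6 mM.
#'
#' @param params A [lan_parameters()] object.
#' @param t_max End of the integration span in hours (> 0); ignored when
#'   `times` is given.
#' @param times Strictly increasing output grid in hours starting at >= 0.
#'   Defaults to hourly from 0 to `t_max`.
#' @param rtol,atol Relative and absolute solver tolerances (defaults 1e-8
#'   and 1e-10).
#' @param actuator_driver Growth driver of the actuator species; see
#'   [lan_rhs()].
#' @return A data frame of class `lan_trajectory` with columns `time_h`,
#'   `cells_S_od`, `cells_R_od`, `fe2_mM`, `fe3_mM`, and attributes
#'   `fe_total` and `clamp_mM`.
#' @examples
#' traj <- simulate_lan(default_truth(), t_max = 96)
#' max(traj$fe2_mM)
#' @export
simulate_lan <- function(params, t_max = 96, times = NULL,
                         rtol = 1e-8, atol = 1e-10,
                         actuator_driver = c("fe3", "fe2")) {
  actuator_driver <- match.arg(actuator_driver)
  stopifnot(inherits(params, "lan_parameters"))
  if (is.null(times)) {
    stopifnot(is.numeric(t_max), length(t_max) == 1L, t_max > 0)
    times <- seq(0, t_max, by = 1)
  }
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (any(times < 0)) stop("output grid must be >= 0")
  if (any(diff(times) <= 0)) stop("output grid must be strictly increasing")

  core <- sim_core(params, times, rtol, atol, actuator_driver)
  if (!is.na(core$t_escape))
    stop(sprintf("ODE integration failed near t = %.3g h (state left the physical region)",
                 core$t_escape))
  sol <- core$sol

  fe2_raw <- sol[, "fe2"]
  fe2 <- pmin(pmax(fe2_raw, 0), params$fe_total)
  clamp <- max(abs(fe2 - fe2_raw))
  if (clamp > 1e-6)
    warning(sprintf("fe2 clamped by up to %.3g mM during post-processing", clamp))

  traj <- data.frame(time_h = sol[, "time"],
                     cells_S_od = sol[, "cells_S"],
                     cells_R_od = sol[, "cells_R"],
                     fe2_mM = fe2,
                     fe3_mM = params$fe_total - fe2)
  attr(traj, "fe_total") <- params$fe_total
  attr(traj, "clamp_mM") <- clamp
  class(traj) <- c("lan_trajectory", "data.frame")
  traj
}

#' Iron conservation check on a trajectory
#'
#' Maximum pointwise deviation of `fe2 + fe3` from the total iron pool.
#' Simulated trajectories return 0 by construction, since Fe3+ is derived;
#' the check is useful on hand-built or round-tripped tables.
#'
#' @param traj A data frame with columns `fe2_mM` and `fe3_mM`.
#' @param fe_total Total iron pool in mM; defaults to the trajectory's
#'   `fe_total` attribute, else 2.
#' @return The maximum absolute deviation in mM.
#' @export
conservation_report <- function(traj, fe_total = NULL) {
  stopifnot(is.data.frame(traj), all(c("fe2_mM", "fe3_mM") %in% names(traj)))
  if (is.null(fe_total))
    fe_total <- if (!is.null(attr(traj, "fe_total"))) attr(traj, "fe_total") else 2
  max(abs(traj$fe2_mM + traj$fe3_mM - fe_total))
}

#' Plot a simulated trajectory
#'
#' Two stacked base-graphics panels: cell densities (OD600) and the iron
#' redox couple (mM).
#'
#' @param x A `lan_trajectory` from [simulate_lan()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.lan_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$time_h, cbind(x$cells_S_od, x$cells_R_od), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "time (h)", ylab = "density (OD600)", ...)
  graphics::legend("topleft", legend = c("router (S)", "actuator (R)"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::matplot(x$time_h, cbind(x$fe2_mM, x$fe3_mM), type = "l",
                    lty = 1, col = c("darkorange", "gray40"),
                    xlab = "time (h)", ylab = "iron (mM)", ...)
  graphics::legend("right", legend = c("Fe2+", "Fe3+"),
                   col = c("darkorange", "gray40"), lty = 1, bty = "n")
  invisible(x)
}
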