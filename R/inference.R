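# Fitting the co-culture model to time-course observations, model-data
# agreement metrics, and small derived quantities.

expand_free <- function(free) {
  blocks <- list(
    growth_S = paste0(c("E", "F", "G", "H", "I"), "_S"),
    growth_R = paste0(c("E", "F", "G", "H", "I"), "_R"),
    ferate_S = paste0(c("J", "K", "L", "M", "N"), "_S"),
    ferate_R = paste0(c("J", "K", "L", "M", "N"), "_R"))
  out <- unlist(lapply(free, function(f) {
    if (f %in% names(blocks)) blocks[[f]] else f
  }), use.names = FALSE)
  unknown <- setdiff(out, sym_names())
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  unique(out)
}

obs_channels <- c("fe2_mM", "cells_S_od", "cells_R_od")

#' Fit the co-culture model to observed time courses
#'
#' Nonlinear least squares (Levenberg--Marquardt) over a chosen subset of
#' model parameters, against any combination of the observable channels
#' `fe2_mM`, `cells_S_od` and `cells_R_od`. Because the channels carry
#' different units, each channel's residuals are standardized by the
#' observed range of that channel before being pooled -- a scaling that is
#' robust on short series. The model is re-simulated (via [simulate_lan()])
#' at every objective evaluation, and the accepted-step rule of
#' Levenberg--Marquardt guarantees the returned residual sum of squares
#' never exceeds the one at the initialization.
#'
#' Jointly fitting all 22 kinetic constants from a single-condition time
#' course is ill-posed; the default frees the two growth blocks and keeps
#' the Fe-rate blocks fixed at their initialization (typically monoculture
#' pre-fits), mirroring how the co-culture model is built on top of the
#' bare-culture ones.
#'
#' @param obs Data frame with a `time_h` column (>= 6 points) and at least
#'   one of the observable channels.
#' @param init A [lan_parameters()] initialization; also supplies the
#'   values of all fixed parameters.
#' @param free Character vector of free parameters: block names
#'   (`"growth_S"`, `"growth_R"`, `"ferate_S"`, `"ferate_R"`) and/or
#'   individual symbols (`"E_S"`, ..., `"N_R"`, `"cells_S0"`, ...).
#' @param lower,upper Optional named bounds on the free parameters;
#'   defaults keep every free parameter positive.
#' @param max_iter Iteration cap; hitting it flags the result as not
#'   converged rather than raising an error.
#' @return A list of class `lan_fit`: `estimate` (a [lan_parameters()]),
#'   `rss` (pooled standardized residual sum of squares), `residuals`
#'   (per-channel list, observation units), `converged`, `n_iter`, `free`.
#' @export
fit_lan_model <- function(obs, init, free = c("growth_S", "growth_R"),
                          lower = NULL, upper = NULL, max_iter = 100L) {
  stopifnot(is.data.frame(obs), inherits(init, "lan_parameters"))
  if (!"time_h" %in% names(obs)) stop("obs must contain a 'time_h' column")
  channels <- intersect(obs_channels, names(obs))
  channels <- channels[vapply(channels, function(ch) !all(is.na(obs[[ch]])), logical(1L))]
  if (!length(channels)) stop("obs contains none of the observable channels")
  times <- obs$time_h
  if (length(times) < 6L) stop("at least 6 time points are required")
  for (ch in channels) {
    if (length(obs[[ch]]) != length(times))
      stop(sprintf("channel '%s' length does not match time_h", ch))
  }

  free_syms <- expand_free(free)
  base <- lan_to_symbols(init)
  p0 <- base[free_syms]
  # two decades below the initialization: keeps parameters positive while
  # leaving the finite-difference Jacobian resolvable everywhere
  if (is.null(lower)) lower <- setNames(pmax(abs(p0) / 100, 1e-10), free_syms)
  if (is.null(upper)) upper <- setNames(rep(Inf, length(p0)), free_syms)

  ranges <- vapply(channels, function(ch) {
    r <- diff(range(obs[[ch]], na.rm = TRUE))
    if (r == 0) 1 else r
  }, numeric(1L))

  n_res <- length(times) * length(channels)
  t_end <- max(times)
  resid_fn <- function(p) {
    syms <- base
    syms[free_syms] <- p
    params <- try(lan_from_symbols(syms), silent = TRUE)
    if (inherits(params, "try-error")) return(rep(1e4, n_res))
    core <- sim_core(params, times)
    if (is.null(core$sol)) {
      # integration collapsed before reaching the grid: flat penalty that
      # shrinks the later the failure occurs, so the optimizer can walk back
      t_esc <- if (is.na(core$t_escape)) 0 else core$t_escape
      return(rep(100 * (1 + (t_end - t_esc) / t_end), n_res))
    }
    traj <- core$sol
    res <- unlist(lapply(channels, function(ch) {
      col <- switch(ch, fe2_mM = "fe2", cells_S_od = "cells_S",
                    cells_R_od = "cells_R")
      (obs[[ch]] - traj[, col]) / ranges[[ch]]
    }), use.names = FALSE)
    res <- pmin(pmax(res, -100), 100)
    if (!is.na(core$t_escape)) {
      # past the escape the frozen values carry no gradient; replace them
      # with a penalty continuous in the escape time so the optimizer is
      # steered back towards the integrable region
      esc <- rep(times > core$t_escape, length(channels))
      res[esc] <- 100 * (1 + (t_end - core$t_escape) / t_end)
    }
    res
  }

  fit <- minpack.lm::nls.lm(par = p0, lower = lower[free_syms],
                            upper = upper[free_syms], fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  est_syms <- base
  est_syms[free_syms] <- fit$par
  estimate <- lan_from_symbols(est_syms)
  traj <- try(suppressWarnings(simulate_lan(estimate, times = times)), silent = TRUE)
  diverged <- inherits(traj, "try-error")
  structure(list(estimate = estimate,
                 rss = fit$deviance,
                 residuals = if (diverged) setNames(rep(list(rep(NA_real_, length(times))),
                                                        length(channels)), channels)
                             else setNames(lapply(channels, function(ch)
                               obs[[ch]] - traj[[ch]]), channels),
                 fitted = if (diverged) NULL else traj,
                 converged = !diverged && fit$info %in% 1:4,
                 n_iter = fit$niter,
                 free = free_syms),
            class = "lan_fit")
}

#' @export
print.lan_fit <- function(x, ...) {
  cat(sprintf("Co-culture model fit: %d free parameter(s) [%s]\n",
              length(x$free), paste(x$free, collapse = ", ")))
  cat(sprintf("  standardized RSS = %.4g, converged = %s, iterations = %d\n",
              x$rss, x$converged, x$n_iter))
  invisible(x)
}

#' Pearson correlation
#'
#' Sample Pearson correlation of two equal-length series, used to quantify
#' model-data agreement per channel.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return The correlation, in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("at least 3 paired values are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: an argument has zero variance")
  cor(x, y)
}

#' Pearson correlation with a p-value
#'
#' Reports the correlation together with the two-sided p-value from the
#' standard t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. No multiple-testing correction is applied.
#'
#' @inheritParams pearson_r
#' @return A list with elements `r`, `p` and `n`.
#' @export
pearson_test <- function(x, y) {
  r <- pearson_r(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Locate the peak of a sampled series
#'
#' Index of the maximum value, with ties broken by the earliest time. A
#' maximum sitting on either boundary of the grid is flagged as not an
#' interior peak (e.g. a still-rising series).
#'
#' @param times Sampling times (>= 3 points).
#' @param values Values at each time.
#' @return A list with `t_peak`, `peak` and logical `interior`.
#' @export
find_peak <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) stop("times and values must have the same length")
  if (length(times) < 3L) stop("at least 3 points are required")
  i <- which.max(values)
  list(t_peak = times[i], peak = values[i],
       interior = i != 1L && i != length(values))
}

#' OD600 to cell count
#'
#' Applies the reporting convention that 1 OD600 unit corresponds to 1e9
#' cells. The co-culture model itself works in OD units; this conversion is
#' applied only at reporting boundaries.
#'
#' @param od OD600 value(s), >= 0.
#' @return Cell count(s).
#' @examples
#' od_to_cells(0.5)
#' @export
od_to_cells <- function(od) {
  stopifnot(is.numeric(od))
  if (any(od < 0)) stop("OD must be >= 0")
  od * 1e9
}

#' Relative abundance of the two species
#'
#' @param cells_S,cells_R Non-negative densities (any common unit) with a
#'   positive sum.
#' @return Named numeric vector `c(fraction_S, fraction_R)` summing to 1.
#' @export
relative_abundance <- function(cells_S, cells_R) {
  stopifnot(is.numeric(cells_S), is.numeric(cells_R),
            length(cells_S) == 1L, length(cells_R) == 1L)
  if (cells_S < 0 || cells_R < 0) stop("densities must be >= 0")
  total <- cells_S + cells_R
  if (total <= 0) stop("composition undefined: total density is zero")
  c(fraction_S = cells_S / total, fraction_R = cells_R / total)
}

#' CO2 fixation rate
#'
#' Bicarbonate consumption normalized by incubation interval and dry cell
#' weight: `consumption / interval / dcw`, in mM per gram per hour.
#'
#' @param bicarbonate_consumed Bicarbonate consumed in mM, >= 0.
#' @param interval Incubation interval in hours, > 0 (default 96).
#' @param dcw Dry cell weight in grams, > 0.
#' @return The fixation rate in mM g^-1 h^-1.
#' @export
co2_fixation_rate <- function(bicarbonate_consumed, interval = 96, dcw) {
  stopifnot(is.numeric(bicarbonate_consumed), is.numeric(interval), is.numeric(dcw))
  if (any(bicarbonate_consumed < 0)) stop("consumption must be >= 0")
  if (any(interval <= 0)) stop("interval must be > 0")
  if (any(dcw <= 0)) stop("dry cell weight must be > 0")
  bicarbonate_consumed / interval / dcw
}

#' Parameter-recovery experiment
#'
#' Monte-Carlo assessment of how faithfully the fitting workflow recovers
#' known model parameters from synthetic observations. For each seed a
#' noisy co-culture series is generated from the truth, the free parameters
#' of the initialization are perturbed multiplicatively, the model is
#' refitted, and model-data agreement is scored per channel with the
#' Pearson correlation between the fitted trajectory and the noisy
#' observations.
#'
#' The default mask frees only the two growth amplitudes (`E_S`, `E_R`),
#' keeping the Fe-rate blocks fixed at truth, as joint estimation of all
#' constants from one condition is ill-posed.
#'
#' @param truth A [lan_parameters()] truth (default [default_truth()]).
#' @param noise A [noise_spec()]; its `seed` field is overridden per
#'   replicate.
#' @param seeds Integer vector of replicate seeds (default 1:25).
#' @param times Sampling grid in hours.
#' @param free Free-parameter mask, as in [fit_lan_model()].
#' @param perturb Half-width of the uniform multiplicative perturbation
#'   applied to the free parameters of the initialization (default 0.15,
#'   i.e. up to +/- 15 %).
#' @return A list of class `recovery_report`: `per_seed` (data frame with
#'   one row per seed: convergence flag, per-channel Pearson R, one column
#'   per free-parameter estimate), `summary` (per-parameter truth, mean
#'   estimate, relative bias and relative RMSE), `median_r` (named
#'   per-channel medians over converged fits), and `free`.
#' @export
recovery_experiment <- function(truth = default_truth(), noise = noise_spec(),
                                seeds = 1:25, times = seq(0, 96, by = 12),
                                free = c("E_S", "E_R"), perturb = 0.15) {
  stopifnot(inherits(truth, "lan_parameters"), inherits(noise, "noise_spec"),
            length(seeds) >= 1L)
  free_syms <- expand_free(free)
  truth_syms <- lan_to_symbols(truth)

  rows <- lapply(seeds, function(sd_i) {
    ns <- noise
    ns$seed <- as.integer(sd_i)
    obs <- generate_coculture_series(truth = truth, times = times, noise = ns)
    set.seed(as.integer(sd_i) + 10000L)
    init_syms <- truth_syms
    init_syms[free_syms] <- init_syms[free_syms] *
      (1 + perturb * runif(length(free_syms), -1, 1))
    fit <- try(fit_lan_model(obs, lan_from_symbols(init_syms), free = free_syms),
               silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit$fitted)) {
      # a wandering fit is recorded per seed, never fatal to the experiment
      return(c(seed = sd_i, converged = 0,
               setNames(rep(NA_real_, length(obs_channels)), obs_channels),
               setNames(rep(NA_real_, length(free_syms)), free_syms)))
    }
    est <- lan_to_symbols(fit$estimate)[free_syms]
    r_ch <- vapply(names(fit$residuals), function(ch)
      pearson_r(obs[[ch]], fit$fitted[[ch]]), numeric(1L))
    c(seed = sd_i, converged = as.numeric(fit$converged), r_ch, est)
  })
  per_seed <- as.data.frame(do.call(rbind, rows))

  ch_cols <- setdiff(names(per_seed), c("seed", "converged", free_syms))
  ok <- per_seed$converged > 0
  median_r <- vapply(ch_cols, function(ch) median(per_seed[[ch]][ok]), numeric(1L))
  summ <- data.frame(
    parameter = free_syms,
    truth = unname(truth_syms[free_syms]),
    mean_estimate = vapply(free_syms, function(s) mean(per_seed[[s]][ok]), numeric(1L)))
  summ$rel_bias <- (summ$mean_estimate - summ$truth) / summ$truth
  summ$rel_rmse <- vapply(seq_along(free_syms), function(i) {
    s <- free_syms[i]
    sqrt(mean(((per_seed[[s]][ok] - summ$truth[i]) / summ$truth[i])^2))
  }, numeric(1L))

  structure(list(per_seed = per_seed, summary = summ,
                 median_r = median_r, free = free_syms),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d seed(s), free: %s\n",
              nrow(x$per_seed), paste(x$free, collapse = ", ")))
  cat("  median Pearson R per channel:\n")
  for (ch in names(x$median_r))
    cat(sprintf("    %-12s %.4f\n", ch, x$median_r[[ch]]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
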