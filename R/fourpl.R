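# Four-parameter logistic (4PL) transduction kinetics.
#
# The monoculture Fe transduction curves are 4PL sigmoids in time:
# Fe2+ accumulating in a bare reducer culture follows the curve directly,
# while a bare oxidizer culture is written for the depleted pool
# fe_total - [Fe2+], so its observable is fe_total minus the sigmoid.

#' Four-parameter logistic curve
#'
#' The sigmoid `f(t) = B + (A - B) / (1 + (t / C)^D)` with early asymptote
#' `A` (value as t -> 0+), late asymptote `B` (t -> infinity),
#' half-transition time `C` (hours, where the curve equals `(A + B)/2`
#' exactly) and shape exponent `D`.
#'
#' @param A,B Early and late asymptotes, in the units of the response.
#' @param C Half-transition time in hours, > 0.
#' @param D Shape exponent, > 0.
#' @return An object of class `fourpl`.
#' @examples
#' p <- fourpl(A = 0, B = 1.6, C = 24, D = 3)
#' fourpl_eval(p, c(0, 24, 96))
#' @export
fourpl <- function(A, B, C, D) {
  vals <- c(A = A, B = B, C = C, D = D)
  if (!all(is.finite(vals)))
    stop("4PL parameters must be finite")
  if (C <= 0) stop("4PL half-transition time C must be > 0")
  if (D <= 0) stop("4PL shape exponent D must be > 0")
  structure(as.list(vals), class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  cat(sprintf("4PL curve: A = %.6g, B = %.6g, C = %.6g h, D = %.6g\n",
              x$A, x$B, x$C, x$D))
  invisible(x)
}

#' Evaluate a four-parameter logistic curve
#'
#' @param params A [fourpl()] object.
#' @param t Time in hours, >= 0. At `t = 0` the power term is 0 (for D > 0)
#'   and the curve returns `A` exactly.
#' @return Numeric vector of curve values, bounded between `min(A, B)` and
#'   `max(A, B)` and monotone in `t`.
#' @export
fourpl_eval <- function(params, t) {
  stopifnot(inherits(params, "fourpl"), is.numeric(t))
  if (any(t < 0)) stop("time must be >= 0")
  params$B + (params$A - params$B) / (1 + (t / params$C)^params$D)
}

#' Monoculture Fe transduction curve
#'
#' Fe2+ concentration over time in a bare monoculture. In the `"router"`
#' role (iron reducer, e.g. *S. putrefaciens*) Fe2+ accumulates and the
#' curve is the 4PL itself; in the `"actuator"` role (iron oxidizer, e.g.
#' *R. palustris*) the 4PL describes the transformed pool
#' `fe_total - [Fe2+]`, so the Fe2+ observable is `fe_total` minus the
#' sigmoid.
#'
#' @param params A [fourpl()] object.
#' @param role `"router"` or `"actuator"`.
#' @param fe_total Total iron pool in mM (default 2).
#' @param t Time in hours, >= 0.
#' @return Fe2+ concentration in mM at each `t`.
#' @export
transduction_curve <- function(params, role = c("router", "actuator"),
                               fe_total = 2, t = seq(0, 96, by = 1)) {
  role <- match.arg(role)
  stopifnot(is.numeric(fe_total), length(fe_total) == 1L, fe_total > 0)
  y <- fourpl_eval(params, t)
  if (role == "router") y else fe_total - y
}

fourpl_resid <- function(par, times, values) {
  values - (par[2L] + (par[1L] - par[2L]) / (1 + (times / par[3L])^par[4L]))
}

#' Fit a four-parameter logistic curve by least squares
#'
#' Levenberg--Marquardt least squares for the 4PL parameters. The fit is
#' deterministic given identical data, initialization and bounds.
#'
#' Initialization, when `init` is absent: `A` is the value at the earliest
#' time, `B` the value at the latest time, `C` the time of closest approach
#' to `(A + B) / 2`, and `D = 2`. Default bounds keep
#' `C` in (0, 10 * max(t)] and `D` in (0, 20], with `A` and `B` inside the
#' observed range widened by one range on each side, which prevents
#' divergence on nearly flat data.
#'
#' Exactly constant data leave the likelihood flat in `(C, D)`; the fit then
#' returns `A = B = value` with the canonical tie-break `C = median(times)`,
#' `D = 1` and is flagged `degenerate`.
#'
#' @param times Sampling times in hours (>= 4 distinct values).
#' @param values Measured response at each time, finite.
#' @param init Optional [fourpl()] initialization.
#' @param lower,upper Optional named bounds vectors `c(A=,B=,C=,D=)`.
#' @param max_iter Iteration cap (default 200); hitting it flags the result
#'   as not converged rather than raising an error.
#' @return A list of class `fourpl_fit` with elements `params` (a
#'   [fourpl()]), `rss`, `residuals`, `converged`, `n_iter` and
#'   `degenerate`.
#' @examples
#' tt <- seq(0, 96, by = 8)
#' y <- fourpl_eval(fourpl(0.05, 1.6, 30, 2.5), tt)
#' fourpl_fit(tt, y)$params
#' @export
fourpl_fit <- function(times, values, init = NULL, lower = NULL, upper = NULL,
                       max_iter = 200L) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 4L || length(unique(times)) < 4L)
    stop("insufficient data: at least 4 distinct time points are required")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (any(times < 0)) stop("time must be >= 0")

  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  vr <- diff(range(values))

  if (vr == 0) {
    pars <- fourpl(values[1L], values[1L], median(times[times > 0]), 1)
    return(structure(list(params = pars, rss = 0,
                          residuals = rep(0, length(values)),
                          converged = TRUE, n_iter = 0L, degenerate = TRUE),
                     class = "fourpl_fit"))
  }

  if (is.null(init)) {
    A0 <- values[1L]
    B0 <- values[length(values)]
    C0 <- times[which.min(abs(values - (A0 + B0) / 2))]
    if (C0 <= 0) C0 <- median(times[times > 0])
    init <- fourpl(A0, B0, C0, 2)
  } else {
    stopifnot(inherits(init, "fourpl"))
  }
  if (is.null(lower))
    lower <- c(A = min(values) - vr, B = min(values) - vr, C = 1e-6, D = 1e-6)
  if (is.null(upper))
    upper <- c(A = max(values) + vr, B = max(values) + vr,
               C = 10 * max(times), D = 20)
  p0 <- pmin(pmax(unlist(init), lower), upper)

  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = fourpl_resid, times = times, values = values,
                            control = minpack.lm::nls.lm.control(maxiter = max_iter))
  est <- fourpl(fit$par[[1L]], fit$par[[2L]], fit$par[[3L]], fit$par[[4L]])
  structure(list(params = est,
                 rss = fit$deviance,
                 residuals = unname(fit$fvec),
                 converged = fit$info %in% 1:4,
                 n_iter = fit$niter,
                 degenerate = FALSE),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  RSS = %.4g, converged = %s, iterations = %d%s\n",
              x$rss, x$converged, x$n_iter,
              if (x$degenerate) " (degenerate constant data)" else ""))
  invisible(x)
}
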