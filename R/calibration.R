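# Linear calibration between probe readout and Fe redox state.
#
# Two instruments share the same machinery: the persistent-luminescence
# nanoprobe, whose log10 intensity is linear in the Fe2+/Fe_total ratio,
# and the o-phenanthroline absorbance assay, linear in Fe2+ concentration.

#' Linear calibration line
#'
#' A straight-line calibration `response = slope * predictor + intercept`.
#' For the luminescence probe the predictor is the Fe2+/Fe_total ratio
#' (percent or fraction) and the response is log10 intensity; for an
#' absorbance standard curve the predictor is a concentration and the
#' convention is `"absolute"`.
#'
#' @param slope Response change per unit predictor. Must be finite; zero is
#'   allowed (a flat standard curve) but such a calibration cannot be
#'   inverted.
#' @param intercept Response at predictor 0.
#' @param convention One of `"percent"` (ratio in 0--100, the default),
#'   `"fraction"` (ratio in 0--1) or `"absolute"` (non-negative predictor
#'   in its own units, e.g. mg/L or mM).
#' @return An object of class `linear_calibration`.
#' @examples
#' cal <- probe_calibration()
#' predict_log_intensity(cal, c(0, 50, 100))
#' @export
linear_calibration <- function(slope, intercept,
                               convention = c("percent", "fraction", "absolute")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, convention = convention),
            class = "linear_calibration")
}

#' Packaged nanoprobe calibration
#'
#' The published log-linear response of the Zn2GeO4:Mn persistent-luminescence
#' probe: log10(intensity) = 0.01764 * C_Fe2+/Fe_total + 2.126, with the
#' ratio expressed in percent (0--100) and Fe_total fixed at 2 mM in the
#' calibration experiment.
#'
#' @return A `linear_calibration` in the percent convention.
#' @export
probe_calibration <- function() {
  linear_calibration(slope = 0.01764, intercept = 2.126, convention = "percent")
}

ratio_range <- function(convention) {
  switch(convention,
         percent  = c(0, 100),
         fraction = c(0, 1),
         absolute = c(0, Inf))
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration (%s convention): response = %.6g * predictor + %.6g\n",
              x$convention, x$slope, x$intercept))
  if (!is.null(attr(x, "r")))
    cat(sprintf("  fit: Pearson R = %.4f, RSS = %.4g, n = %d\n",
                attr(x, "r"), attr(x, "rss"), attr(x, "n")))
  invisible(x)
}

#' Forward calibration: predictor to response
#'
#' Evaluates the calibration line, `slope * ratio + intercept`. For the
#' luminescence probe this is the predicted log10 intensity at a given
#' Fe2+/Fe_total ratio.
#'
#' @param calib A [linear_calibration()].
#' @param ratio Numeric vector of predictor values, inside the calibration's
#'   convention range (0--100 for percent, 0--1 for fraction, >= 0 for
#'   absolute).
#' @return Numeric vector of responses.
#' @export
predict_log_intensity <- function(calib, ratio) {
  stopifnot(inherits(calib, "linear_calibration"), is.numeric(ratio))
  rng <- ratio_range(calib$convention)
  bad <- !is.na(ratio) & (ratio < rng[1] | ratio > rng[2])
  if (any(bad)) {
    stop(sprintf("ratio %g outside the '%s' convention range [%g, %g]",
                 ratio[which(bad)[1]], calib$convention, rng[1], rng[2]))
  }
  calib$slope * ratio + calib$intercept
}

#' Inverse calibration: response to predictor
#'
#' Inverts the calibration line, `(response - intercept) / slope`. Values
#' falling outside the convention range (as measurement noise can push
#' readouts slightly past the calibrated range) are clipped to it and
#' flagged rather than rejected.
#'
#' @param calib A [linear_calibration()] with nonzero slope.
#' @param log_intensity Numeric vector of responses (log10 intensity for the
#'   luminescence probe).
#' @return Numeric vector of predictor values with a logical attribute
#'   `"clipped"` marking entries that were clipped into the convention
#'   range. A warning is raised if any clipping occurred.
#' @export
invert_to_ratio <- function(calib, log_intensity) {
  stopifnot(inherits(calib, "linear_calibration"), is.numeric(log_intensity))
  if (calib$slope == 0)
    stop("calibration has zero slope and is not invertible")
  raw <- (log_intensity - calib$intercept) / calib$slope
  rng <- ratio_range(calib$convention)
  out <- pmin(pmax(raw, rng[1]), rng[2])
  clipped <- !is.na(raw) & (raw < rng[1] | raw > rng[2])
  if (any(clipped))
    warning(sprintf("%d readout(s) outside the calibrated range were clipped", sum(clipped)))
  attr(out, "clipped") <- clipped
  out
}

#' Fe2+ concentration from a raw luminescence readout
#'
#' Converts raw luminescence counts to the Fe2+ (and companion Fe3+)
#' concentration of a closed iron pool: the log10 intensity is inverted to
#' a Fe2+/Fe_total ratio through the calibration line and scaled by the
#' total iron concentration. Fe3+ is derived as `fe_total - fe2`.
#'
#' @param calib A ratio-convention [linear_calibration()] (percent or
#'   fraction) with nonzero slope.
#' @param intensity Positive raw luminescence counts.
#' @param fe_total Total iron concentration in mM (default 2, the pool used
#'   in the calibration experiments).
#' @return A data frame with columns `fe2_mM` and `fe3_mM`.
#' @examples
#' fe2_from_intensity(probe_calibration(), 10^3.008, fe_total = 2)
#' @export
fe2_from_intensity <- function(calib, intensity, fe_total = 2) {
  stopifnot(inherits(calib, "linear_calibration"), is.numeric(intensity),
            is.numeric(fe_total), length(fe_total) == 1L, fe_total > 0)
  if (calib$convention == "absolute")
    stop("fe2_from_intensity needs a ratio-convention calibration (percent or fraction)")
  if (any(!is.na(intensity) & intensity <= 0))
    stop("intensity must be positive (log10 undefined otherwise)")
  ratio <- invert_to_ratio(calib, log10(intensity))
  scale <- if (calib$convention == "percent") 100 else 1
  fe2 <- fe_total * as.numeric(ratio) / scale
  data.frame(fe2_mM = fe2, fe3_mM = fe_total - fe2)
}

#' Fit a linear calibration by ordinary least squares
#'
#' Fits `response = slope * predictor + intercept` to standard-curve pairs,
#' e.g. log10 luminescence against known Fe2+/Fe_total ratios, or
#' absorbance at 510 nm against known Fe2+ concentrations in the
#' o-phenanthroline assay.
#'
#' @param predictor,response Numeric vectors of equal length (>= 2 pairs,
#'   with at least two distinct predictor values).
#' @param convention Convention recorded on the returned calibration; see
#'   [linear_calibration()].
#' @param log10_response If `TRUE`, the response is a raw (positive)
#'   intensity that is log10-transformed before fitting; zero or negative
#'   intensities are rejected rather than offset-shifted.
#' @return A `linear_calibration` carrying the fit diagnostics as
#'   attributes: `r` (Pearson correlation of predictor and response),
#'   `rss` (residual sum of squares), `residuals`, and `n`.
#' @export
fit_linear_calibration <- function(predictor, response,
                                   convention = c("percent", "fraction", "absolute"),
                                   log10_response = FALSE) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(predictor), is.numeric(response))
  if (length(predictor) != length(response))
    stop("predictor and response must have the same length")
  if (length(predictor) < 2L)
    stop("insufficient data: at least 2 calibration pairs are required")
  if (any(!is.finite(predictor)) || any(!is.finite(response)))
    stop("calibration pairs must be finite")
  if (length(unique(predictor)) < 2L)
    stop("degenerate design: all predictor values are identical")
  if (log10_response) {
    if (any(response <= 0))
      stop("raw intensities must be positive to take log10")
    response <- log10(response)
  }
  fit <- lm(response ~ predictor)
  cal <- linear_calibration(unname(coef(fit)[2L]), unname(coef(fit)[1L]),
                            convention = convention)
  res <- unname(fit$residuals)
  attr(cal, "rss") <- sum(res^2)
  attr(cal, "residuals") <- res
  attr(cal, "n") <- length(predictor)
  attr(cal, "r") <- if (sd(response) > 0) cor(predictor, response) else NA_real_
  cal
}
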