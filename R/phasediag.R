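# Phase-diagram critical-concentration estimation ----------------------------
#
# Both titration readouts (condensed volume fraction in bulk, condensed
# area fraction on the bilayer) are fitted with a straight line through the
# points with positive response; the critical concentration is the line's
# intersection with the concentration axis.

#' Critical concentration by axis intersection
#'
#' Fits `fraction ~ concentration` through the titration points with
#' positive response (replicates pooled) and returns the x-intercept as the
#' saturation concentration, with a standard error propagated from the
#' slope/intercept covariance. Points with zero response sit below the
#' transition and are excluded from the fit.
#'
#' @param concentration bulk concentrations (nM), strictly positive.
#' @param fraction condensed fraction responses in `[0, 1]`, same length.
#' @return list with `c_sat` (nM, clamped at >= 0), `c_sat_se`, `slope`,
#'   `n_points` and `clamped` (TRUE if the raw intercept was negative).
#' @examples
#' cc <- c(1000, 2000, 5000)
#' estimate_csat(cc, 0.001 * (cc - 500))$c_sat
#' @export
estimate_csat <- function(concentration, fraction) {
  if (length(concentration) != length(fraction))
    stop("'concentration' and 'fraction' lengths differ")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(fraction < 0 | fraction > 1))
    stop("fractions must lie in [0, 1]")
  keep <- fraction > 0
  cc <- concentration[keep]
  ff <- fraction[keep]
  if (length(unique(cc)) < 2L)
    stop("need at least 2 distinct concentrations with positive response")
  fit <- stats::lm(ff ~ cc)
  b <- unname(stats::coef(fit))
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("no condensation trend: fitted slope is not positive")
  raw <- -b[1] / b[2]
  V <- stats::vcov(fit)
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  clamped <- raw < 0
  list(c_sat = max(raw, 0), c_sat_se = se, slope = b[2],
       n_points = length(cc), clamped = clamped)
}

#' Condensed fraction of a field of view
#'
#' @param mask label (or logical) mask; nonzero pixels are condensed.
#' @return fraction of masked pixels in `[0, 1]`.
#' @export
condensed_fraction <- function(mask) {
  mean(mask > 0)
}
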