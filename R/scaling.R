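# Cross-concentration scaling analysis ---------------------------------------
#
# Onset-time vs bulk-concentration power law, rescaling of mean surface
# intensities to a relative surface-concentration scale, and the test for a
# common surface concentration at the moment of prewetting.

#' Power-law fit of onset time versus bulk concentration
#'
#' OLS of log t_pw on log c_b. First-order adsorption with a common
#' critical surface concentration predicts exponent -1.
#'
#' @param c_b bulk concentrations (nM), positive.
#' @param t_pw onset times (s), positive, same length.
#' @return object of class `power_law_fit`: list with `exponent`,
#'   `exponent_se` (`NA` with fewer than 3 points), `prefactor`, `n_points`.
#' @examples
#' fit_onset_scaling(c(100, 250, 500), 2000 / c(100, 250, 500))$exponent
#' @export
fit_onset_scaling <- function(c_b, t_pw) {
  if (length(c_b) != length(t_pw)) stop("'c_b' and 't_pw' lengths differ")
  if (length(c_b) < 2L) stop("need at least 2 (c_b, t_pw) pairs")
  if (any(c_b <= 0) || any(t_pw <= 0))
    stop("concentrations and onset times must be positive")
  lx <- log(c_b)
  ly <- log(t_pw)
  if (length(c_b) == 2L) {
    expo <- diff(ly) / diff(lx)
    return(structure(list(exponent = expo, exponent_se = NA_real_,
                          prefactor = exp(ly[1] - expo * lx[1]),
                          n_points = 2L),
                     class = "power_law_fit"))
  }
  fit <- stats::lm(ly ~ lx)
  co <- summary(fit)$coefficients
  structure(list(exponent = unname(co[2, 1]), exponent_se = unname(co[2, 2]),
                 prefactor = exp(unname(co[1, 1])),
                 n_points = length(c_b)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law: exponent = %.3f +/- %.3f (n = %d)\n",
              x$exponent, x$exponent_se, x$n_points))
  invisible(x)
}

#' Rescale mean-intensity traces to surface concentrations
#'
#' Determines the single rescaling factor rho0 such that the reference
#' condition's intensity trace plateaus, after rescaling, at its own bulk
#' concentration in A.U. (e.g. the 100 nM reference plateaus at 100 A.U.),
#' then applies that rho0 to every condition: `c_s(t) = rho0 * I_s(t)`.
#' The plateau is the mean of the final 10% of frames, accepted only if the
#' relative change over that tail is below 1%.
#'
#' @param traces data.frame with columns `c_b` (nM), `time` (s),
#'   `intensity` (A.U., background-referenced mean intensity).
#' @param reference_c_b bulk concentration of the reference condition; must
#'   be present in `traces`.
#' @param plateau_frac tail fraction used for the plateau.
#' @param plateau_tol maximum relative change over the tail.
#' @return list with `rho0` and `traces` (the input with an added `c_s`
#'   column).
#' @export
rescale_to_surface_concentration <- function(traces, reference_c_b,
                                             plateau_frac = 0.1,
                                             plateau_tol = 0.01) {
  need <- c("c_b", "time", "intensity")
  if (!all(need %in% names(traces)))
    stop("'traces' needs columns c_b, time, intensity")
  ref <- traces[traces$c_b == reference_c_b, ]
  if (nrow(ref) == 0L) stop("reference condition not present in 'traces'")
  ref <- ref[order(ref$time), ]
  n_tail <- max(2L, ceiling(plateau_frac * nrow(ref)))
  tail_i <- ref$intensity[seq.int(nrow(ref) - n_tail + 1L, nrow(ref))]
  plateau <- mean(tail_i)
  if (plateau <= 0 ||
      (max(tail_i) - min(tail_i)) / plateau > plateau_tol)
    stop("reference trace has not reached a plateau")
  rho0 <- reference_c_b / plateau
  traces$c_s <- rho0 * traces$intensity
  list(rho0 = rho0, traces = traces)
}

#' Surface concentration at the onset of prewetting
#'
#' Evaluates each condition's rescaled surface-concentration trace at its
#' prewetting time (linear interpolation) and reports the spread across
#' conditions. A small coefficient of variation supports a common critical
#' surface concentration.
#'
#' @param rescaled the result of [rescale_to_surface_concentration()] (or
#'   its `traces` data.frame with a `c_s` column).
#' @param onset data.frame with columns `c_b` and `t_pw` (s).
#' @return list with `per_condition` (data.frame c_b, t_pw, c_s_at_onset)
#'   and `cv`, the coefficient of variation across conditions.
#' @export
surface_concentration_at_onset <- function(rescaled, onset) {
  traces <- if (is.data.frame(rescaled)) rescaled else rescaled$traces
  if (!"c_s" %in% names(traces))
    stop("'rescaled' must carry a c_s column (run the rescaling first)")
  if (!all(c("c_b", "t_pw") %in% names(onset)))
    stop("'onset' needs columns c_b and t_pw")
  cs <- numeric(nrow(onset))
  for (i in seq_len(nrow(onset))) {
    tr <- traces[traces$c_b == onset$c_b[i], ]
    if (nrow(tr) == 0L)
      stop(sprintf("no trace for c_b = %g", onset$c_b[i]))
    if (onset$t_pw[i] < min(tr$time) || onset$t_pw[i] > max(tr$time))
      stop(sprintf("t_pw = %g s outside the trace support for c_b = %g",
                   onset$t_pw[i], onset$c_b[i]))
    cs[i] <- stats::approx(tr$time, tr$c_s, xout = onset$t_pw[i])$y
  }
  list(per_condition = data.frame(c_b = onset$c_b, t_pw = onset$t_pw,
                                  c_s_at_onset = cs),
       cv = .cv(cs))
}
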