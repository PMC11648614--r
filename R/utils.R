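# Shared numerical helpers.

# Smoothing-spline refinement used by both onset metrics: a cubic smoothing
# spline with smoothing chosen by generalized cross-validation, evaluated on
# a regular fine grid (default 1 s). `deriv = 1` returns the analytic
# derivative of the fitted spline.
.spline_refine <- function(times, values, step = 1, deriv = 0) {
  if (length(times) < 4L)
    stop("spline refinement needs at least 4 frames")
  if (length(times) != length(values))
    stop("times and values must have equal length")
  fit <- stats::smooth.spline(times, values)
  grid <- seq(min(times), max(times), by = step)
  list(time = grid, value = stats::predict(fit, grid, deriv = deriv)$y)
}

.assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < min)
    stop(sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}

# coefficient of variation
.cv <- function(x) stats::sd(x) / mean(x)
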