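# Histogram-bimodality onset metric ------------------------------------------
#
# Per frame, the logarithm of pixel intensities is binned into a probability
# distribution P(x) on bin edges fixed across the whole series. A
# one-component and a two-component Gaussian density are fitted by least
# squares on F(x) * dx vs P(x); the residue difference
# r0(t) = r1(t) - r2(t) is ~0 while the distribution is unimodal and jumps
# when a condensed branch splits off. The switch time is the first crossing
# of r0 above a threshold on a spline-refined 1 s grid.

#' Global log-intensity bin edges for a series
#'
#' 100 uniform bins spanning the 0.1-99.9 intensity percentile span of the
#' stack (in log units), fixed across frames so residues are comparable
#' over time. The span is taken per frame and then enveloped (minimum of
#' the per-frame 0.1 percentiles to maximum of the per-frame 99.9
#' percentiles): pooled whole-stack percentiles would cut several percent
#' off the dimmest frame's lower tail whenever later frames are much
#' brighter, and that truncation masquerades as skew in the residue
#' statistic. Intensities are floored at `floor_eps` before the log to
#' avoid -Inf from dark pixels; the default floor is 1e-3 of the stack's
#' median intensity.
#'
#' @param series an [acquisition_series()] (or 3-d array).
#' @param n_bins number of bins.
#' @param probs length-2 percentile pair defining the span.
#' @param floor_eps positive intensity floor (A.U.); `NULL` for the default.
#' @return list with `edges` (length `n_bins + 1`) and `floor_eps`.
#' @export
stack_bin_edges <- function(series, n_bins = 100L, probs = c(0.001, 0.999),
                            floor_eps = NULL) {
  frames <- if (inherits(series, "acquisition_series")) series$frames
            else series
  if (is.null(floor_eps)) {
    med <- stats::median(frames[frames > 0])
    floor_eps <- 1e-3 * med
  }
  if (!is.numeric(floor_eps) || floor_eps <= 0)
    stop("'floor_eps' must be positive")
  x <- log(pmax(frames, floor_eps))
  nT <- dim(x)[3]
  qf <- vapply(seq_len(nT), function(f)
    stats::quantile(x[, , f], probs, names = FALSE), numeric(2))
  q <- c(min(qf[1, ]), max(qf[2, ]))
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-6
  list(edges = seq(q[1], q[2], length.out = n_bins + 1L),
       floor_eps = floor_eps)
}

#' Log-intensity histogram of one frame
#'
#' Probability mass per bin of the log pixel intensities, on fixed global
#' bin edges. Pixels outside the global bin range (below the 0.1 or above
#' the 99.9 stack percentile by default) are excluded and the masses
#' normalised over the in-range pixels, so every histogram sums to exactly
#' 1; clamping them into the edge bins instead would fabricate a spurious
#' second mode in the dimmest frames.
#'
#' @param frame numeric matrix of pixel intensities (A.U.).
#' @param bin_edges uniform bin edges in log-intensity units.
#' @param floor_eps positive intensity floor applied before the log.
#' @param time optional frame time (s), stored for bookkeeping.
#' @return object of class `intensity_histogram`: list with `x` (bin
#'   centers), `dx` (bin width), `p` (probability masses), `n` (pixel
#'   count), `time`.
#' @export
log_intensity_histogram <- function(frame, bin_edges, floor_eps,
                                    time = NA_real_) {
  if (!is.numeric(floor_eps) || length(floor_eps) != 1L || floor_eps <= 0)
    stop("'floor_eps' must be a positive number")
  nb <- length(bin_edges) - 1L
  x <- log(pmax(frame, floor_eps))
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx <= nb]
  if (length(idx) == 0L)
    stop("no pixels fall inside the bin range")
  counts <- tabulate(idx, nbins = nb)
  structure(list(x = (bin_edges[-1] + bin_edges[-(nb + 1L)]) / 2,
                 dx = bin_edges[2] - bin_edges[1],
                 p = counts / length(idx), n = length(idx), time = time),
            class = "intensity_histogram")
}

# residue of a Gaussian mixture against a histogram:
# sum over bins of (F(x) * dx - P(x))^2
.mix_residue <- function(hist, w, m, s) {
  f <- rep(0, length(hist$x))
  for (k in seq_along(w)) f <- f + w[k] * stats::dnorm(hist$x, m[k], s[k])
  sum((f * hist$dx - hist$p)^2)
}

#' Fit a one- or two-component Gaussian density to a histogram
#'
#' Least-squares fit of `F(x) * dx` to the probability masses `P(x)`, where
#' `F` is a unit-mass Gaussian (or weighted sum of two). The residue is
#' `r = sum((F(x) dx - P(x))^2)`. The one-component fit starts from
#' histogram moments; the two-component fit is multi-start (the
#' one-component solution split by +/- 1 sd, and a 25th/90th-percentile
#' start) and always also considers the collapsed candidate equal to the
#' one-component solution, so the two-component residue can never exceed
#' the one-component one. Components are ordered by increasing mean.
#'
#' @param hist an [log_intensity_histogram()] result.
#' @param n_components 1 or 2.
#' @return object of class `gaussian_fit`: list with `n_components`,
#'   `weights`, `means`, `sds`, `residue`.
#' @export
fit_gaussians <- function(hist, n_components = 1L) {
  if (!inherits(hist, "intensity_histogram"))
    stop("'hist' must be an intensity_histogram")
  if (!n_components %in% c(1L, 2L))
    stop("'n_components' must be 1 or 2")
  x <- hist$x
  p <- hist$p
  dx <- hist$dx
  m0 <- sum(x * p)
  s0 <- max(sqrt(max(sum(p * (x - m0)^2), 0)), dx / 3)

  if (n_components == 1L) {
    obj <- function(par) .mix_residue(hist, 1, par[1], exp(par[2]))
    starts <- list(c(m0, log(s0)), c(m0, log(s0 * 3)), c(m0, log(dx / 2)))
    best <- NULL
    for (st in starts) {
      op <- tryCatch(stats::optim(st, obj, control = list(maxit = 500,
                                                          reltol = 1e-12)),
                     error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("one-component Gaussian fit did not converge")
    return(structure(list(n_components = 1L, weights = 1,
                          means = best$par[1], sds = exp(best$par[2]),
                          residue = best$value),
                     class = "gaussian_fit"))
  }

  if (sum(p > 0) < 10L)
    stop("two-component fit needs at least 10 non-empty bins")
  fit1 <- fit_gaussians(hist, 1L)
  m1 <- fit1$means
  s1 <- fit1$sds
  cum <- cumsum(p)
  q25 <- x[which(cum >= 0.25)[1]]
  q90 <- x[which(cum >= 0.90)[1]]
  obj <- function(par) {
    w <- stats::plogis(par[1])
    .mix_residue(hist, c(w, 1 - w), par[2:3], exp(par[4:5]))
  }
  starts <- list(
    c(0, m1 - s1, m1 + s1, log(s1), log(s1)),
    c(stats::qlogis(0.7), q25, q90, log(max(s1 / 2, dx / 3)),
      log(max(s1 / 2, dx / 3))),
    c(stats::qlogis(0.9), m1, q90, log(s1), log(max(s1, dx / 3)))
  )
  best <- NULL
  diag <- list()
  for (st in starts) {
    op <- tryCatch(stats::optim(st, obj, control = list(maxit = 1000,
                                                        reltol = 1e-12)),
                   error = function(e) NULL)
    diag[[length(diag) + 1L]] <- op
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    e <- simpleError("two-component Gaussian fit did not converge")
    e$diagnostics <- diag
    stop(e)
  }
  # collapsed candidate: both components at the one-component solution
  # (identical density, residue r1) guarantees r2 <= r1
  if (best$value > fit1$residue) {
    return(structure(list(n_components = 2L, weights = c(0.5, 0.5),
                          means = c(m1, m1), sds = c(s1, s1),
                          residue = fit1$residue),
                     class = "gaussian_fit"))
  }
  w <- stats::plogis(best$par[1])
  means <- best$par[2:3]
  sds <- exp(best$par[4:5])
  o <- order(means)
  structure(list(n_components = 2L, weights = c(w, 1 - w)[o],
                 means = means[o], sds = sds[o], residue = best$value),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit (%d component%s), residue %.3g\n",
              x$n_components, if (x$n_components > 1) "s" else "", x$residue))
  for (k in seq_len(x$n_components))
    cat(sprintf("  w = %.3f, mean = %.3f, sd = %.3f\n",
                x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

#' Residue-difference trace r0(t)
#'
#' `r0(t) = r1(t) - r2(t)`, the per-frame difference between the
#' one-component and two-component fit residues. Because the two-component
#' fit always contains the one-component solution as a candidate, the
#' difference is non-negative on every frame (nested least squares).
#'
#' @param fits1 list of one-component [fit_gaussians()] results, one per frame.
#' @param fits2 list of two-component results, same length.
#' @return numeric vector of residue differences, one per frame.
#' @export
residue_difference_trace <- function(fits1, fits2) {
  if (length(fits1) != length(fits2))
    stop("fit lists must have equal length (one pair per frame)")
  r1 <- vapply(fits1, function(f) f$residue, numeric(1))
  r2 <- vapply(fits2, function(f) f$residue, numeric(1))
  r0 <- r1 - r2
  stopifnot(all(r0 >= -1e-15))
  pmax(r0, 0)
}

#' Histogram residue-difference trace for a whole series
#'
#' Convenience wrapper: global bin edges, per-frame histograms, paired
#' one-/two-component fits, and the resulting r0(t).
#'
#' @param series an [acquisition_series()].
#' @param n_bins number of histogram bins.
#' @return list with `r0` (per frame), `times`, `hists`, `fits1`, `fits2`.
#' @export
histogram_residue_trace <- function(series, n_bins = 100L) {
  be <- stack_bin_edges(series, n_bins = n_bins)
  hists <- lapply(seq_len(n_frames(series)), function(f)
    log_intensity_histogram(series$frames[, , f], be$edges, be$floor_eps,
                            time = series$times[f]))
  fits1 <- lapply(hists, fit_gaussians, n_components = 1L)
  fits2 <- lapply(hists, fit_gaussians, n_components = 2L)
  list(r0 = residue_difference_trace(fits1, fits2), times = series$times,
       hists = hists, fits1 = fits1, fits2 = fits2)
}

#' Raw switch time from a residue-difference trace
#'
#' The trace is refined from the native frame sampling to a 1 s grid by a
#' GCV smoothing spline (clamped at 0, since r0 is non-negative by
#' construction); the raw switch time is the first grid time at which the
#' refined trace exceeds the threshold.
#'
#' @param r0_trace per-frame residue differences (or any onset statistic).
#' @param threshold positive detection threshold.
#' @param frame_times frame times (s), at least 4.
#' @param step refinement step (s).
#' @return the raw switch time (s), or `NA_real_` if the threshold is never
#'   exceeded.
#' @export
detect_switch_time <- function(r0_trace, threshold, frame_times, step = 1) {
  .assert_scalar_num(threshold, "threshold")
  if (threshold <= 0) stop("'threshold' must be positive")
  ref <- .spline_refine(frame_times, r0_trace, step = step)
  v <- pmax(ref$value, 0)
  i <- which(v > threshold)[1]
  if (is.na(i)) NA_real_ else ref$time[i]
}

#' Reversal time of the histogram split
#'
#' First refined time after the raw switch at which r0 falls back below the
#' threshold and remains below it for a dwell of `dwell_frames` frame
#' intervals. A dip whose dwell window runs past the end of the
#' acquisition cannot be certified as a reversal and is ignored.
#'
#' @param r0_trace per-frame residue differences.
#' @param threshold detection threshold (same as used for the switch).
#' @param frame_times frame times (s).
#' @param t_hat_pw raw switch time from [detect_switch_time()].
#' @param dwell_frames dwell length in frame intervals.
#' @param step refinement step (s).
#' @return reversal time (s) or `NA_real_` if the split is maintained.
#' @export
detect_reversal_time <- function(r0_trace, threshold, frame_times, t_hat_pw,
                                 dwell_frames = 3, step = 1) {
  if (is.na(t_hat_pw)) stop("reversal detection requires a detected switch")
  ref <- .spline_refine(frame_times, r0_trace, step = step)
  v <- pmax(ref$value, 0)
  dwell_s <- dwell_frames * stats::median(diff(frame_times))
  cand <- which(ref$time > t_hat_pw & v < threshold &
                  ref$time + dwell_s <= max(ref$time))
  for (i in cand) {
    horizon <- ref$time <= ref$time[i] + dwell_s & ref$time >= ref$time[i]
    if (all(v[horizon] < threshold)) return(ref$time[i])
  }
  NA_real_
}

#' Acquisition delay from early adsorption kinetics
#'
#' Fits a straight line to the background-referenced mean intensity within
#' the first 0-30 s of acquisition and returns its x-intercept as the delay
#' t0. With first-order adsorption the mean intensity is proportional to
#' the time since bulk addition, so the intercept locates that moment on
#' the acquisition clock; it is negative when kinetics already ran before
#' frame 0.
#'
#' @param times frame times (s).
#' @param intensity mean intensity trace (A.U.).
#' @param background constant background/camera offset to subtract (A.U.).
#' @param window fit window c(lo, hi) in s.
#' @return delay t0 (s); warns when negative.
#' @export
estimate_delay <- function(times, intensity, background = 0,
                           window = c(0, 30)) {
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3L)
    stop("delay estimation needs at least 3 frames in the fit window")
  fit <- stats::lm(I(intensity[sel] - background) ~ times[sel])
  b <- unname(stats::coef(fit))
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("no association signal: fitted slope is not positive")
  t0 <- -b[1] / b[2]
  if (t0 < -1e-8)
    warning(sprintf("negative delay t0 = %.2f s (kinetics preceded frame 0)",
                    t0))
  t0
}

#' Threshold-sensitivity range of the prewetting time
#'
#' Re-detects the switch at 0.9x and 1.1x the threshold and returns the
#' delay-corrected pair ordered as (low, high). If the switch is lost at a
#' varied threshold the range is open-ended: the lost side is `NA` and the
#' attribute `open_ended` is set.
#'
#' @param r0_trace per-frame residue differences.
#' @param threshold central detection threshold.
#' @param frame_times frame times (s).
#' @param t0 delay correction (s) subtracted from both ends.
#' @param step refinement step (s).
#' @return numeric c(low, high) in s, possibly with attribute `open_ended`.
#' @export
threshold_sensitivity <- function(r0_trace, threshold, frame_times, t0 = 0,
                                  step = 1) {
  t_c <- detect_switch_time(r0_trace, threshold, frame_times, step = step)
  if (is.na(t_c)) stop("no switch detected at the central threshold")
  t_lo <- detect_switch_time(r0_trace, 0.9 * threshold, frame_times,
                             step = step)
  t_hi <- detect_switch_time(r0_trace, 1.1 * threshold, frame_times,
                             step = step)
  rng <- sort(c(t_lo, t_hi), na.last = TRUE) - t0
  if (anyNA(rng)) {
    warning("switch lost at a varied threshold: open-ended range")
    attr(rng, "open_ended") <- TRUE
  }
  rng
}
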