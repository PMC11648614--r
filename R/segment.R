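# Condensate segmentation and layer-index estimation ------------------------
#
# Condensates are bright objects on a dim, spatially uniform adsorbed layer,
# so a robust background + k*sigma threshold followed by connected-component
# labelling is adequate; the per-condensate table of integrated area and
# integrated intensity then feeds the layer-index power-law fit.

#' Segment condensates in a single frame
#'
#' Foreground pixels are those brighter than
#' `background_level + k_sigma * sigma`, where `sigma` is a robust (MAD)
#' estimate of the background noise. With `background_level = "auto"` the
#' background is taken as the mode of the log-intensity histogram mapped
#' back to the linear scale — the adsorbed layer dominates the pixel
#' population, so its level is the histogram mode. Connected components
#' smaller than `min_area` pixels are discarded and labels relabelled
#' contiguously from 1.
#'
#' @param frame numeric matrix of pixel intensities (A.U.), finite-valued.
#' @param background_level background intensity (A.U.) or `"auto"`.
#' @param k_sigma threshold multiplier on the robust background sd.
#' @param min_area minimum component area in pixels.
#' @return Integer label matrix (0 = background) of class `label_mask`, with
#'   attributes `background` and `threshold`.
#' @export
segment_condensates <- function(frame, background_level = "auto",
                                k_sigma = 4, min_area = 4L) {
  if (!is.matrix(frame) || !all(is.finite(frame)))
    stop("'frame' must be a finite-valued numeric matrix")
  bg <- if (identical(background_level, "auto")) {
    .auto_background(frame)
  } else {
    .assert_scalar_num(background_level, "background_level")
  }
  sigma <- stats::mad(frame, center = bg)
  thr <- bg + k_sigma * sigma
  fg <- frame > thr
  if (all(fg)) {
    warning("threshold below the whole frame: returning an empty mask")
    fg[] <- FALSE
  }
  lab <- EBImage::bwlabel(fg * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(frame), ncol(frame))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  structure(lab, class = c("label_mask", class(lab)),
            background = bg, threshold = thr)
}

# mode of the log-intensity histogram, mapped back to linear scale
.auto_background <- function(frame, n_bins = 256L) {
  pos <- frame[frame > 0]
  if (length(pos) == 0L) return(0)
  eps <- 1e-3 * stats::median(pos)
  x <- log(pmax(frame, eps))
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  exp(h$mids[which.max(h$counts)])
}

#' Tabulate per-condensate area and integrated intensity
#'
#' For each label: integrated area `A` = pixel count x pixel_size^2,
#' integrated intensity `V` = sum of background-subtracted intensities over
#' the label (clamped at >= 0), centroid in um, and equivalent radius
#' `r_eq = sqrt(A / pi)`.
#'
#' @param frame numeric matrix of pixel intensities (A.U.).
#' @param mask label matrix from [segment_condensates()] (same shape).
#' @param pixel_size pixel edge length (um).
#' @param background_level background intensity to subtract (A.U.); defaults
#'   to the mask's stored background.
#' @return data.frame with columns id, n_px, area_um2, intensity_au, x_um,
#'   y_um, r_eq_um; empty (zero rows) for an empty mask.
#' @export
tabulate_condensates <- function(frame, mask, pixel_size,
                                 background_level = attr(mask, "background")) {
  if (!all(dim(frame) == dim(mask)))
    stop("'mask' must match the frame shape")
  if (is.null(background_level)) background_level <- 0
  empty <- data.frame(id = integer(), n_px = integer(), area_um2 = numeric(),
                      intensity_au = numeric(), x_um = numeric(),
                      y_um = numeric(), r_eq_um = numeric())
  n_lab <- max(mask)
  if (n_lab == 0L) return(empty)
  idx <- which(mask > 0L)
  lab <- mask[idx]
  n_px <- tabulate(lab, nbins = n_lab)
  vsum <- as.numeric(rowsum(frame[idx] - background_level, lab))
  rows <- (idx - 1L) %% nrow(frame) + 1L
  cols <- (idx - 1L) %/% nrow(frame) + 1L
  x_um <- as.numeric(rowsum((cols - 1) * pixel_size, lab)) / n_px
  y_um <- as.numeric(rowsum((rows - 1) * pixel_size, lab)) / n_px
  area <- n_px * pixel_size^2
  data.frame(id = seq_len(n_lab), n_px = n_px, area_um2 = area,
             intensity_au = pmax(vsum, 0), x_um = x_um, y_um = y_um,
             r_eq_um = sqrt(area / pi))
}

#' Condensate number density over time
#'
#' @param series an [acquisition_series()] (used for frame times).
#' @param masks list of label masks, one per frame.
#' @param field_area field-of-view area (um^2); defaults to the series'
#'   geometry.
#' @return data.frame with columns time (s), count, density (per um^2).
#' @export
number_density_trace <- function(series, masks, field_area = NULL) {
  if (length(masks) != n_frames(series))
    stop("one mask per frame required")
  if (is.null(field_area)) {
    d <- dim(series$frames)
    field_area <- prod((d[1:2] - 1L) * series$pixel_size)
  }
  counts <- vapply(masks, function(m) as.integer(max(m)), integer(1))
  data.frame(time = series$times, count = counts,
             density = counts / field_area)
}

#' Segment every frame of a series
#'
#' @param series an [acquisition_series()].
#' @param ... passed to [segment_condensates()].
#' @return list of label masks, one per frame.
#' @export
segment_series <- function(series, ...) {
  lapply(seq_len(n_frames(series)),
         function(f) segment_condensates(series$frames[, , f], ...))
}

#' Layer index from a condensate table
#'
#' Ordinary least squares of log integrated intensity on log integrated
#' area. The slope is the layer index: 1 for condensates of uniform
#' (monolayer) thickness, 1.5 for spherical caps of fixed contact angle.
#' Rows with non-positive intensity are excluded (and counted) because their
#' logarithm is undefined.
#'
#' @param table data.frame with columns `area_um2` and `intensity_au` (the
#'   output of [tabulate_condensates()] or the generator's truth table).
#' @return object of class `layer_index_fit`: list with `alpha`, `alpha_se`,
#'   `prefactor`, `n_condensates`, `n_excluded`.
#' @examples
#' tab <- data.frame(area_um2 = seq(0.5, 5, length.out = 30))
#' tab$intensity_au <- 400 * tab$area_um2^1.5
#' layer_index(tab)$alpha
#' @export
layer_index <- function(table) {
  if (!all(c("area_um2", "intensity_au") %in% names(table)))
    stop("'table' needs columns area_um2 and intensity_au")
  ok <- table$intensity_au > 0 & table$area_um2 > 0
  n_excluded <- sum(!ok)
  tab <- table[ok, ]
  if (nrow(tab) < 3L)
    stop("layer index fit needs at least 3 condensates with positive intensity")
  la <- log(tab$area_um2)
  if (stats::var(la) == 0)
    stop("layer index fit needs variation in condensate area")
  fit <- stats::lm(log(intensity_au) ~ la, data = tab)
  co <- summary(fit)$coefficients
  structure(list(alpha = unname(co[2, 1]), alpha_se = unname(co[2, 2]),
                 prefactor = exp(unname(co[1, 1])),
                 n_condensates = nrow(tab), n_excluded = n_excluded),
            class = "layer_index_fit")
}

#' @export
print.layer_index_fit <- function(x, ...) {
  cat(sprintf("layer index: alpha = %.3f +/- %.3f (n = %d, %d excluded)\n",
              x$alpha, x$alpha_se, x$n_condensates, x$n_excluded))
  invisible(x)
}
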