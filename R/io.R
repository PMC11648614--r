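# Stack I/O: multi-page TIFF + JSON sidecar ----------------------------------

#' Write an acquisition series to disk
#'
#' Frames go to a multi-page 16-bit TIFF (rescaled by a factor stored in the
#' sidecar), metadata (times, pixel size, bulk concentration, baseline,
#' intensity scale) to a JSON sidecar next to it.
#'
#' @param series an [acquisition_series()].
#' @param dir output directory (created if missing).
#' @param name base file name (without extension).
#' @return invisibly, the paths written.
#' @export
write_acquisition_series <- function(series, dir, name = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(series$frames, 1e-12)
  pages <- lapply(seq_len(n_frames(series)), function(f)
    pmin(pmax(series$frames[, , f] / scale, 0), 1))
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  meta <- list(times = series$times, pixel_size = series$pixel_size,
               c_b = series$c_b, baseline = series$baseline,
               intensity_scale = scale)
  js <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif, json = js))
}

#' Read an acquisition series written by [write_acquisition_series()]
#'
#' @param dir directory holding the pair of files.
#' @param name base file name.
#' @return an [acquisition_series()].
#' @export
read_acquisition_series <- function(dir, name = "stack") {
  tif <- file.path(dir, paste0(name, ".tif"))
  js <- file.path(dir, paste0(name, ".json"))
  pages <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    frames[, , f] <- pages[[f]] * meta$intensity_scale
  acquisition_series(frames, times = meta$times,
                     pixel_size = meta$pixel_size,
                     c_b = if (is.null(meta$c_b)) NA_real_ else meta$c_b,
                     baseline = if (is.null(meta$baseline)) 0
                                else meta$baseline)
}

#' Write a condensate table as CSV
#'
#' @param table data.frame from [tabulate_condensates()].
#' @param path output CSV path.
#' @export
write_condensate_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
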