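#' Write and read spectral images
#'
#' The quantitative grid is written as a single-channel 32-bit TIFF
#' scaled by the image maximum, with a JSON sidecar (`<path>.json`)
#' holding the metadata and the scale factor; quantisation is below
#' 2^-32 of the image maximum, so round-trips are lossless to well past
#' single precision and exact for images whose maximum pixel is the only
#' non-zero level.  With `display_log10 = TRUE` an additional
#' `<stem>_display.tif` rendering with `log10(1 + value)` scaling is
#' written for visualization; the quantitative file is never
#' log-scaled.
#'
#' @param image a [spectral_image()].
#' @param path output TIFF path.
#' @param display_log10 also write the log-scaled display rendering.
#' @return `write_image`: `path`, invisibly.  `read_image`: the
#'   `spectral_image`.
#' @export
write_image <- function(image, path, display_log10 = FALSE) {
  stopifnot(inherits(image, "spectral_image"))
  mx <- max(image$grid)
  scale_factor <- if (mx > 0) mx else 1
  tiff::writeTIFF(image$grid / scale_factor, path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(mode = image$mode, scale = image$scale,
               units = image$units,
               acquisition_time_s = image$acquisition_time_s,
               pixel_pitch_um = image$pixel_pitch_um,
               normalized = image$normalized,
               scale_factor = scale_factor)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (display_log10) {
    disp <- log10_display(image$grid)
    dmx <- max(disp)
    tiff::writeTIFF(if (dmx > 0) disp / dmx else disp,
                    sub("\\.tiff?$", "_display.tif", path),
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  # undo the 32-bit quantisation: stored sample k/2^32 encodes the
  # level k/(2^32 - 1) of the full scale
  k <- round(tiff::readTIFF(path) * 2^32)
  g <- k / (2^32 - 1) * meta$scale_factor
  spectral_image(g, meta$mode, meta$scale, meta$units,
                 meta$acquisition_time_s, normalized = meta$normalized)
}

#' Display log scaling
#'
#' `log10(1 + value)`: the visualization transform applied to event-map
#' images so individual particle tracks remain visible next to bright
#' sources; maps 0, 9, 99 to 0, 1, 2.
#'
#' @param values non-negative numeric vector or matrix.
#' @return Transformed values, same shape.
#' @export
log10_display <- function(values) log10(1 + values)
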