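#' Spectral image container
#'
#' A 256 x 256 non-negative raster with its reconstruction metadata.
#' `grid[r + 1, c + 1]` holds pixel (col = c, row = r) in the 0-based
#' detector convention; physical position of a pixel centre is
#' `(index + 0.5) * 55 um` from the top-left corner, giving the
#' 1.4 x 1.4 cm field of view.
#'
#' @param grid 256 x 256 numeric matrix, all values >= 0.
#' @param mode `"event_map"` or `"centroid"`.
#' @param scale `"activity"` or `"spectroscopic"`.
#' @param units unit string (e.g. `"events/s/pixel"`, `"MeV/s/mm2"`).
#' @param acquisition_time_s acquisition duration, seconds.
#' @param normalized logical: has time(/area) normalization been applied?
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(grid, mode, scale, units,
                           acquisition_time_s, normalized = FALSE) {
  mode <- match.arg(mode, c("event_map", "centroid"))
  scale <- match.arg(scale, c("activity", "spectroscopic"))
  if (!is.matrix(grid) || !all(dim(grid) == QPID_GRID))
    stop("grid must be a 256 x 256 matrix", call. = FALSE)
  if (any(grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  structure(list(grid = grid, mode = mode, scale = scale, units = units,
                 acquisition_time_s = acquisition_time_s,
                 pixel_pitch_um = QPID_PITCH_UM,
                 normalized = isTRUE(normalized)),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("spectral_image: %s / %s, %s; sum %.6g; t = %g s\n",
              x$mode, x$scale, x$units, sum(x$grid),
              x$acquisition_time_s))
  invisible(x)
}

#' @export
plot.spectral_image <- function(x, log10_scale = TRUE, ...) {
  g <- if (log10_scale) log10_display(x$grid) else x$grid
  graphics::image(t(g)[, QPID_GRID:1], col = grDevices::gray(seq(0, 1, 0.01)),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

PIXEL_AREA_MM2 <- (QPID_PITCH_UM / 1000)^2  # 3.025e-3 mm^2

#' Reconstruct an autoradiography image from tracks
#'
#' Increment rules: in `event_map`/`activity` every member pixel of a
#' track gains `1/N` (N = pixels in the track); in `centroid`/`activity`
#' the pixel containing the energy-weighted centroid gains 1; the
#' `spectroscopic` scale replaces these with the per-pixel deposited
#' energy and the full track energy respectively.  With
#' `normalize = TRUE` the activity grid is divided by the acquisition
#' time (events/s/pixel) and the spectroscopic grid by time and pixel
#' area in MeV/s/mm2.  Before normalization the activity grid sums to
#' the number of tracks and the spectroscopic grid to the total
#' deposited energy.
#'
#' @param tracks a `qpid_tracks` object.
#' @param mode `"event_map"` or `"centroid"`.
#' @param scale `"activity"` or `"spectroscopic"`.
#' @param acquisition_time_s acquisition duration, seconds.
#' @param normalize apply the time(/area) normalization (default `TRUE`).
#' @param mask optional dead-pixel data frame (`col`, `row`); masked
#'   pixels stay zero and centroids landing on them move to the nearest
#'   unmasked pixel.
#' @return A [spectral_image()].
#' @export
reconstruct_image <- function(tracks, mode = c("event_map", "centroid"),
                              scale = c("activity", "spectroscopic"),
                              acquisition_time_s, normalize = TRUE,
                              mask = NULL) {
  mode <- match.arg(mode); scale <- match.arg(scale)
  stopifnot(inherits(tracks, "qpid_tracks"), acquisition_time_s > 0)
  g <- matrix(0, QPID_GRID, QPID_GRID)
  s <- tracks$summary
  if (nrow(s)) {
    if (mode == "event_map") {
      h <- tracks$hits
      h <- h[h$track_id %in% s$track_id, , drop = FALSE]
      npix <- s$n_pixels[match(h$track_id, s$track_id)]
      val <- if (scale == "activity") 1 / npix else h$energy_kev
      idx <- h$row + 1L + h$col * QPID_GRID  # column-major linear index
      acc <- rowsum(val, idx)
      g[as.integer(rownames(acc))] <- acc[, 1L]
    } else {
      pc <- pmin(pmax(floor(s$centroid_col), 0L), QPID_GRID - 1L)
      pr <- pmin(pmax(floor(s$centroid_row), 0L), QPID_GRID - 1L)
      if (!is.null(mask) && nrow(mask)) {
        bad <- paste(pc, pr) %in% paste(mask$col, mask$row)
        for (i in which(bad)) {
          mv <- nearest_unmasked(pc[i], pr[i], mask)
          pc[i] <- mv[1L]; pr[i] <- mv[2L]
        }
        if (any(bad))
          message(sum(bad), " centroid(s) moved off masked pixels")
      }
      val <- if (scale == "activity") rep(1, nrow(s)) else s$energy_kev
      idx <- pr + 1L + pc * QPID_GRID
      acc <- rowsum(val, idx)
      g[as.integer(rownames(acc))] <- acc[, 1L]
    }
    if (mode == "event_map" && !is.null(mask) && nrow(mask))
      g[cbind(mask$row + 1L, mask$col + 1L)] <- 0
  }
  if (normalize) {
    if (scale == "activity") {
      g <- g / acquisition_time_s
      units <- "events/s/pixel"
    } else {
      g <- g / 1000 / acquisition_time_s / PIXEL_AREA_MM2
      units <- "MeV/s/mm2"
    }
  } else {
    units <- if (scale == "activity") "events/pixel" else "keV/pixel"
  }
  spectral_image(g, mode, scale, units, acquisition_time_s,
                 normalized = normalize)
}

nearest_unmasked <- function(c0, r0, mask) {
  mk <- paste(mask$col, mask$row)
  for (rad in 1:8) {
    cand <- expand.grid(col = (c0 - rad):(c0 + rad),
                        row = (r0 - rad):(r0 + rad))
    cand <- cand[cand$col >= 0 & cand$col < QPID_GRID &
                   cand$row >= 0 & cand$row < QPID_GRID, ]
    cand <- cand[!(paste(cand$col, cand$row) %in% mk), ]
    if (nrow(cand)) {
      d <- (cand$col - c0)^2 + (cand$row - r0)^2
      return(c(cand$col[which.min(d)], cand$row[which.min(d)]))
    }
  }
  c(c0, r0)
}

#' Scale a time-normalized activity image to Bq per pixel
#'
#' @param image an activity-scale, time-normalized [spectral_image()].
#' @param calibration_factor Bq per (event/s).
#' @return The scaled `spectral_image` (units `"Bq/pixel"`).
#' @export
to_activity_units <- function(image, calibration_factor) {
  stopifnot(inherits(image, "spectral_image"), calibration_factor > 0)
  if (image$scale != "activity" || !image$normalized)
    stop("to_activity_units() needs a time-normalized activity image",
         call. = FALSE)
  image$grid <- image$grid * calibration_factor
  image$units <- "Bq/pixel"
  image$calibration_factor <- calibration_factor
  image
}

#' Convert an activity image to cell density
#'
#' Divides decay-corrected Bq/pixel by the labelling specific activity
#' to obtain cells per pixel, then by the pixel volume
#' (pitch^2 x thickness) to express cells per microlitre.
#'
#' @param image a Bq/pixel `spectral_image` (see [to_activity_units()]).
#' @param specific_activity_bq_per_cell labelling specific activity,
#'   Bq per cell (e.g. 17.6 kBq per 10^6 cells = 0.0176).
#' @param thickness_um section thickness, micrometres (> 0).
#' @return A `spectral_image` in `"cells/uL"`.
#' @export
to_cell_density <- function(image, specific_activity_bq_per_cell,
                            thickness_um) {
  stopifnot(inherits(image, "spectral_image"),
            specific_activity_bq_per_cell > 0)
  if (thickness_um <= 0) stop("thickness must be > 0", call. = FALSE)
  vol_ul <- PIXEL_AREA_MM2 * (thickness_um / 1000)  # mm^3 == uL
  image$grid <- image$grid / specific_activity_bq_per_cell / vol_ul
  image$units <- "cells/uL"
  image
}

#' Line profile and its FWHM
#'
#' Averages the image over a band of the given width perpendicular to
#' the segment from `start` to `end` (fractional pixel coordinates,
#' `c(col, row)`), and measures the profile's full width at half maximum
#' by linear interpolation at the outermost half-max crossings,
#' converted to micrometres with the 55 um pitch.
#'
#' @param image a [spectral_image()].
#' @param start,end segment endpoints, `c(col, row)` in pixels.
#' @param width_px band width for perpendicular averaging (default 3).
#' @param step_px sampling step along the segment (default 1, the pixel
#'   resolution of the data; sub-pixel crossing positions come from a
#'   cubic-spline refinement of the sampled profile).
#' @return List with `distance_um`, `profile`, `fwhm_um`.
#' @export
line_profile_fwhm <- function(image, start, end, width_px = 3,
                              step_px = 1) {
  stopifnot(inherits(image, "spectral_image"))
  d <- sqrt(sum((end - start)^2))
  if (d <= 0) stop("degenerate profile segment", call. = FALSE)
  u <- (end - start) / d
  v <- c(-u[2L], u[1L])
  s_along <- seq(0, d, by = step_px)
  offs <- seq(-width_px / 2, width_px / 2, by = 0.5)
  prof <- vapply(s_along, function(s) {
    p <- start + s * u
    mean(vapply(offs, function(o)
      bilinear_at(image$grid, p[1L] + o * v[1L], p[2L] + o * v[2L]),
      numeric(1)))
  }, numeric(1))
  if (max(prof) <= min(prof))
    stop("flat profile: FWHM undefined", call. = FALSE)
  base <- min(prof)
  if (length(s_along) >= 4L) {
    fine <- stats::spline(s_along, prof - base,
                          xout = seq(0, d, by = step_px / 50))
    fy <- pmax(fine$y, 0); fx <- fine$x
  } else {
    fy <- prof - base; fx <- s_along
  }
  above <- which(fy >= max(fy) / 2)
  fwhm_px <- fx[above[length(above)]] - fx[above[1L]]
  list(distance_um = s_along * QPID_PITCH_UM, profile = prof,
       fwhm_um = fwhm_px * QPID_PITCH_UM)
}

# Bilinear interpolation at fractional pixel (col = x, row = y);
# outside the grid the image is taken as 0.
bilinear_at <- function(grid, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(c_, r_) {
    if (c_ < 0 || c_ >= QPID_GRID || r_ < 0 || r_ >= QPID_GRID) 0
    else grid[r_ + 1L, c_ + 1L]
  }
  (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
}

#' Region-of-interest statistics
#'
#' Per-ROI pixel mean and standard error of the mean; when a ROI is
#' labelled `"background"` its mean is subtracted from the other ROIs'
#' means (`mean_bg_sub`).  Overlap between the background ROI and a
#' target ROI triggers a warning.
#'
#' @param image a [spectral_image()].
#' @param rois named list of 256 x 256 logical masks (see [roi_rect()],
#'   [roi_circle()]).
#' @return Data frame: `label`, `n_pixels`, `mean`, `sem`,
#'   `mean_bg_sub`.
#' @export
roi_statistics <- function(image, rois) {
  stopifnot(inherits(image, "spectral_image"), length(rois) >= 1,
            !is.null(names(rois)))
  for (m in rois)
    if (!is.logical(m) || !all(dim(m) == QPID_GRID) || !any(m))
      stop("each ROI must be a non-empty 256 x 256 logical mask",
           call. = FALSE)
  bg <- rois[["background"]]
  if (!is.null(bg))
    for (lab in setdiff(names(rois), "background"))
      if (any(bg & rois[[lab]]))
        warning("ROI '", lab, "' overlaps the background ROI")
  stats <- lapply(names(rois), function(lab) {
    v <- image$grid[rois[[lab]]]
    data.frame(label = lab, n_pixels = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  out$sem[out$n_pixels == 1L] <- 0
  bg_mean <- if (is.null(bg)) 0 else out$mean[out$label == "background"]
  out$mean_bg_sub <- ifelse(out$label == "background", 0,
                            out$mean - bg_mean)
  out
}

#' @rdname roi_statistics
#' @param col0,col1,row0,row1 inclusive 0-based bounds of a rectangle.
#' @export
roi_rect <- function(col0, col1, row0, row1) {
  m <- matrix(FALSE, QPID_GRID, QPID_GRID)
  m[(row0:row1) + 1L, (col0:col1) + 1L] <- TRUE
  m
}

#' @rdname roi_statistics
#' @param cx,cy,r circle centre and radius, pixels.
#' @export
roi_circle <- function(cx, cy, r) {
  idx <- expand.grid(row = 0:(QPID_GRID - 1L), col = 0:(QPID_GRID - 1L))
  m <- matrix((idx$col - cx)^2 + (idx$row - cy)^2 <= r^2,
              QPID_GRID, QPID_GRID)
  m
}
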