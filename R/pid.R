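#' Particle-identification configuration
#'
#' Default thresholds follow the instrument's filter settings: betas
#' deposit less than ~1 MeV, alphas carry a high-energy threshold of
#' 3 MeV plus a circular-topology requirement, and the beta-plus filter
#' additionally demands a coincident gamma above 450 keV (the
#' annihilation photopeak selection).
#'
#' @param beta_max_kev upper energy bound for beta tracks (default 1000).
#' @param alpha_min_kev lower energy bound for alpha tracks (default
#'   3000); must exceed `beta_max_kev`.
#' @param gamma_min_kev lower energy bound on the coincident gamma in the
#'   beta-plus filter (default 450).
#' @param elongation_min,fill_min circularity decision thresholds on the
#'   shape metrics (defaults 0.6 each).
#' @return A `pid_config` list.
#' @export
pid_config <- function(beta_max_kev = 1000, alpha_min_kev = 3000,
                       gamma_min_kev = 450, elongation_min = 0.6,
                       fill_min = 0.6) {
  stopifnot(beta_max_kev > 0, alpha_min_kev > beta_max_kev,
            gamma_min_kev > 0)
  structure(list(beta_max_kev = beta_max_kev,
                 alpha_min_kev = alpha_min_kev,
                 gamma_min_kev = gamma_min_kev,
                 elongation_min = elongation_min, fill_min = fill_min),
            class = "pid_config")
}

#' Topology metrics of a pixel track
#'
#' `elongation` is `sqrt(lambda_minor / lambda_major)` of the
#' energy-weighted second-moment matrix of the member pixel positions:
#' 1 for a circular blob, toward 0 for a line.  `fill_fraction` is the
#' pixel count over the number of lattice pixels inside the filled
#' convex hull of the track: compact discs score near 1, jagged sparse
#' walks score low.  A single-pixel track scores (1, 1); for collinear
#' tracks the hull degenerates to the segment and the fill denominator
#' is its Chebyshev length.
#'
#' @param track_hits data frame of member hits (`col`, `row`,
#'   `energy_kev`).
#' @return Named numeric vector `c(elongation, fill_fraction)`.
#' @export
track_shape_metrics <- function(track_hits) {
  n <- nrow(track_hits)
  stopifnot(n >= 1)
  if (n == 1L) return(c(elongation = 1, fill_fraction = 1))
  x <- track_hits$col; y <- track_hits$row
  w <- track_hits$energy_kev / sum(track_hits$energy_kev)
  mx <- sum(w * x); my <- sum(w * y)
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  cxy <- sum(w * (x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  elong <- if (ev[1L] <= 1e-12) 1 else sqrt(ev[2L] / ev[1L])
  c(elongation = elong,
    fill_fraction = min(n / hull_pixel_count(x, y), 1))
}

# Number of lattice points inside (or on) the filled convex hull of the
# pixel set; collinear sets degenerate to their Chebyshev span + 1.
hull_pixel_count <- function(x, y) {
  pts <- unique(data.frame(x = x, y = y))
  n <- nrow(pts)
  span <- max(max(pts$x) - min(pts$x), max(pts$y) - min(pts$y)) + 1L
  if (n <= 2L) return(span)
  h <- grDevices::chull(pts$x, pts$y)
  if (length(h) <= 2L) return(span)  # collinear
  hx <- pts$x[h]; hy <- pts$y[h]
  # orient counter-clockwise
  if (sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy) < 0) {
    hx <- rev(hx); hy <- rev(hy)
  }
  cand <- expand.grid(x = min(pts$x):max(pts$x), y = min(pts$y):max(pts$y))
  inside <- rep(TRUE, nrow(cand))
  k <- length(hx)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (cand$y - hy[i]) -
      (hy[j] - hy[i]) * (cand$x - hx[i])
    inside <- inside & cross >= -1e-9
  }
  max(sum(inside), span)
}

#' Classify tracks as alpha, beta or unknown
#'
#' A track is `alpha` when it is circular by the shape decision rule
#' (elongation and fill fraction both at or above their thresholds) and
#' its energy is at least the alpha threshold; `beta` when its energy is
#' at or below the beta threshold; `unknown` otherwise.  Beta-minus and
#' beta-plus tracks are indistinguishable in shape and energy; only the
#' gamma coincidence (see [beta_plus_filter()]) separates them.
#'
#' @param tracks a `qpid_tracks` object.
#' @param config a [pid_config()].
#' @return `tracks` with `elongation`, `fill_fraction` and `pid` columns
#'   added to the summary.
#' @export
classify_tracks <- function(tracks, config = pid_config()) {
  stopifnot(inherits(tracks, "qpid_tracks"))
  s <- tracks$summary
  if (nrow(s)) {
    sm <- vapply(split(tracks$hits, tracks$hits$track_id),
                 track_shape_metrics, numeric(2))
    i <- match(s$track_id, as.integer(colnames(sm)))
    s$elongation <- sm[1L, i]
    s$fill_fraction <- sm[2L, i]
    s$pid <- classify_track(s$energy_kev, s$elongation, s$fill_fraction,
                            config)
  } else {
    s$elongation <- numeric(); s$fill_fraction <- numeric()
    s$pid <- character()
  }
  tracks$summary <- s
  tracks$pid_config <- config
  tracks
}

#' @rdname classify_tracks
#' @param energy_kev,elongation,fill_fraction per-track values (vectors
#'   recycle).
#' @return `classify_track`: character vector in
#'   `{"alpha", "beta", "unknown"}`.
#' @export
classify_track <- function(energy_kev, elongation, fill_fraction,
                           config = pid_config()) {
  circular <- elongation >= config$elongation_min &
    fill_fraction >= config$fill_min
  ifelse(circular & energy_kev >= config$alpha_min_kev, "alpha",
         ifelse(energy_kev <= config$beta_max_kev, "beta", "unknown"))
}

#' Beta-plus selection filter
#'
#' Keeps tracks whose energy is at or below the beta threshold AND that
#' carry a coincident gamma at or above the gamma energy threshold
#' (defaults 1 MeV and 450 keV).  Requires [match_coincidences()] to
#' have run.
#'
#' @param tracks a `qpid_tracks` object with coincidence columns.
#' @param config a [pid_config()].
#' @return The filtered `qpid_tracks`.
#' @export
beta_plus_filter <- function(tracks, config = pid_config()) {
  stopifnot(inherits(tracks, "qpid_tracks"))
  if (is.null(tracks$summary$gamma_energy_kev))
    stop("run match_coincidences() before the beta-plus filter",
         call. = FALSE)
  s <- tracks$summary
  keep <- s$energy_kev <= config$beta_max_kev &
    !is.na(s$gamma_energy_kev) &
    s$gamma_energy_kev >= config$gamma_min_kev
  subset_tracks(tracks, keep)
}

#' Alpha selection filter
#'
#' Keeps tracks labelled `alpha` by [classify_tracks()] (classifying
#' first if needed).
#' @inheritParams beta_plus_filter
#' @return The filtered `qpid_tracks`.
#' @export
alpha_filter <- function(tracks, config = pid_config()) {
  if (is.null(tracks$summary$pid)) tracks <- classify_tracks(tracks, config)
  subset_tracks(tracks, tracks$summary$pid == "alpha")
}

#' Inclusive energy-window filter
#'
#' Keeps tracks with `lo_kev <= energy <= hi_kev` (both bounds
#' inclusive), e.g. the 5-20 keV window selecting 12.7 keV Auger tracks.
#'
#' @param tracks a `qpid_tracks` object.
#' @param lo_kev,hi_kev window bounds, keV, `lo_kev < hi_kev`.
#' @return The filtered `qpid_tracks`.
#' @export
energy_window_filter <- function(tracks, lo_kev, hi_kev) {
  stopifnot(inherits(tracks, "qpid_tracks"), lo_kev < hi_kev)
  subset_tracks(tracks, tracks$summary$energy_kev >= lo_kev &
                  tracks$summary$energy_kev <= hi_kev)
}

# Subset a qpid_tracks by a logical over summary rows; track ids are
# preserved for traceability.
subset_tracks <- function(tracks, keep) {
  keep[is.na(keep)] <- FALSE
  out <- tracks
  out$summary <- tracks$summary[keep, , drop = FALSE]
  out$hits <- tracks$hits[tracks$hits$track_id %in%
                            out$summary$track_id, , drop = FALSE]
  rownames(out$summary) <- rownames(out$hits) <- NULL
  out
}
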