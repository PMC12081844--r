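#' Track aggregation configuration
#'
#' Hits are joined into one ionization track when they are near-adjacent
#' in space (Chebyshev pixel distance at most `radius_px`) and close in
#' time (within `time_window_ns`), with transitive chain linking: a track
#' may span more than one window end-to-end when consecutive links each
#' fall inside it.
#'
#' @param time_window_ns pairwise coincidence window, ns (default 40,
#'   set from the 22 ns FWTM of the intra-track timing distribution).
#' @param radius_px Chebyshev adjacency radius in pixels (default 2,
#'   bridging diagonal steps and single dead pixels).
#' @param min_pixels minimum track size kept (default 1).
#' @return An `aggregation_config` list.
#' @export
aggregation_config <- function(time_window_ns = 40, radius_px = 2,
                               min_pixels = 1) {
  stopifnot(time_window_ns > 0, radius_px >= 1, min_pixels >= 1)
  structure(list(time_window_ns = time_window_ns, radius_px = radius_px,
                 min_pixels = min_pixels), class = "aggregation_config")
}

#' Cluster pixel hits into ionization tracks
#'
#' Connected components of the graph joining two hits when their time
#' difference is within the aggregation window AND their Chebyshev pixel
#' distance is within the adjacency radius.  Clustering uses union-find
#' over time-sorted hits, so the partition is independent of input
#' order.  Every hit belongs to exactly one track; tracks are returned
#' sorted by track time.
#'
#' @param hits a calibrated `qpid_hits` data frame.
#' @param config an [aggregation_config()].
#' @param mask optional dead-pixel mask: data frame with `col`, `row` of
#'   pixels to drop before clustering.
#' @return An object of class `qpid_tracks`: list with `summary` (one row
#'   per track: `track_id`, `n_pixels`, `energy_kev`, `time_ns`,
#'   `centroid_col`, `centroid_row`) and `hits` (the input hits with a
#'   `track_id` column).
#' @export
build_tracks <- function(hits, config = aggregation_config(),
                         mask = NULL) {
  if (!is_calibrated(hits))
    stop("hits carry raw ToT values; apply apply_pixel_energy_calibration() first",
         call. = FALSE)
  if (!is.null(mask) && nrow(mask)) {
    drop <- paste(hits$col, hits$row) %in% paste(mask$col, mask$row)
    hits <- hits[!drop, , drop = FALSE]
  }
  n <- nrow(hits)
  if (n == 0L)
    return(structure(list(summary = empty_track_summary(),
                          hits = cbind(as.data.frame(hits),
                                       track_id = integer()),
                          config = config), class = "qpid_tracks"))
  o <- order(hits$toa_ns, hits$col, hits$row)
  h <- as.data.frame(hits)[o, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  toa <- h$toa_ns; cc <- h$col; rr <- h$row
  w <- config$time_window_ns; rad <- config$radius_px
  start <- 1L
  for (i in 2:max(n, 2L)) {
    if (i > n) break
    while (toa[i] - toa[start] > w) start <- start + 1L
    if (start < i) {
      js <- start:(i - 1L)
      near <- js[pmax(abs(cc[js] - cc[i]), abs(rr[js] - rr[i])) <= rad]
      for (j in near) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab <- match(root, unique(root))
  en <- h$energy_kev
  k <- max(lab)
  npix <- tabulate(lab, k)
  e_tot <- as.numeric(rowsum(en, lab))
  t_mean <- as.numeric(rowsum(toa, lab)) / npix
  cx <- as.numeric(rowsum(en * cc, lab)) / e_tot
  cy <- as.numeric(rowsum(en * rr, lab)) / e_tot
  ord <- order(t_mean)
  rank <- match(seq_len(k), ord)
  summary <- data.frame(track_id = seq_len(k), n_pixels = npix[ord],
                        energy_kev = e_tot[ord], time_ns = t_mean[ord],
                        centroid_col = cx[ord], centroid_row = cy[ord])
  h$track_id <- rank[lab]
  keep <- summary$n_pixels >= config$min_pixels
  if (!all(keep)) {
    kept_ids <- summary$track_id[keep]
    summary <- summary[keep, , drop = FALSE]
    summary$track_id <- seq_len(nrow(summary))
    h <- h[h$track_id %in% kept_ids, , drop = FALSE]
    h$track_id <- match(h$track_id, kept_ids)
  }
  rownames(summary) <- rownames(h) <- NULL
  structure(list(summary = summary, hits = h, config = config),
            class = "qpid_tracks")
}

empty_track_summary <- function() {
  data.frame(track_id = integer(), n_pixels = integer(),
             energy_kev = numeric(), time_ns = numeric(),
             centroid_col = numeric(), centroid_row = numeric())
}

#' @export
print.qpid_tracks <- function(x, ...) {
  cat(sprintf("qpid_tracks: %d tracks from %d hits (window %g ns, radius %g px)\n",
              nrow(x$summary), nrow(x$hits), x$config$time_window_ns,
              x$config$radius_px))
  if (nrow(x$summary)) {
    cat(sprintf("  energy: median %.3g keV, range [%.3g, %.3g] keV\n",
                stats::median(x$summary$energy_kev),
                min(x$summary$energy_kev), max(x$summary$energy_kev)))
    if (!is.null(x$summary$pid))
      print(table(pid = x$summary$pid))
  }
  invisible(x)
}

#' Summaries of a single track
#'
#' Energy is the sum of member pixel energies; time is the unweighted
#' mean of member hit times; the centroid is the energy-weighted mean of
#' the member pixel coordinates, in fractional pixel units.
#'
#' @param track_hits data frame of the member hits (`col`, `row`,
#'   `toa_ns`, `energy_kev`).
#' @return List with `energy_kev`, `time_ns`, `centroid`
#'   (`c(col, row)`), `n_pixels`.
#' @export
summarize_track <- function(track_hits) {
  stopifnot(nrow(track_hits) >= 1)
  e <- sum(track_hits$energy_kev)
  if (e <= 0) stop("zero total energy: centroid undefined", call. = FALSE)
  list(energy_kev = e,
       time_ns = mean(track_hits$toa_ns),
       centroid = c(col = sum(track_hits$energy_kev * track_hits$col) / e,
                    row = sum(track_hits$energy_kev * track_hits$row) / e),
       n_pixels = nrow(track_hits))
}

#' Intra-track time residual histogram
#'
#' Histogram of (hit time - track mean time) over all member hits of all
#' multi-pixel tracks; its width (see [hist_width()]) is the single-track
#' aggregation time resolution.
#'
#' @param tracks a `qpid_tracks` object.
#' @param bin_ns histogram bin width, ns (default: the 1.5625 ns time
#'   quantum).
#' @return An `energy_spectrum` over residual time, ns.
#' @export
intra_track_time_residuals <- function(tracks, bin_ns = QPID_TIME_QUANTUM_NS) {
  stopifnot(inherits(tracks, "qpid_tracks"))
  h <- tracks$hits
  multi <- tracks$summary$track_id[tracks$summary$n_pixels >= 2L]
  h <- h[h$track_id %in% multi, , drop = FALSE]
  if (!nrow(h)) stop("no tracks with >= 2 pixels", call. = FALSE)
  t_track <- tracks$summary$time_ns[match(h$track_id,
                                          tracks$summary$track_id)]
  bin_spectrum(h$toa_ns - t_track, bin_ns)
}
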