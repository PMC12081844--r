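# Shared fixtures and independent oracles, all built in code.

# Brute-force clustering oracle: BFS over the full pairwise adjacency
# matrix (|dt| <= window AND Chebyshev distance <= radius), independent
# of the union-find implementation under test.
oracle_partition <- function(hits, window_ns, radius_px) {
  n <- nrow(hits)
  adj <- abs(outer(hits$toa_ns, hits$toa_ns, "-")) <= window_ns &
    pmax(abs(outer(hits$col, hits$col, "-")),
         abs(outer(hits$row, hits$row, "-"))) <= radius_px
  lab <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(lab[j])) next
      lab[j] <- k
      queue <- c(queue, which(adj[j, ] & is.na(lab)))
    }
  }
  lab
}

# Partition as a canonical set-of-sets over a hit id column.
partition_sets <- function(ids, labels) {
  unname(lapply(split(ids, labels), function(s) sort(s)))
}

same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = ","),
           lapply(b, paste, collapse = ","))
}

# Random hit field over a small pixel patch with clustered times.
random_hit_field <- function(n, patch = 40, t_span_ns = 3000) {
  pixel_hits(col = sample.int(patch, n, replace = TRUE) - 1L,
             row = sample.int(patch, n, replace = TRUE) - 1L,
             toa_ns = runif(n, 0, t_span_ns),
             energy = runif(n, 5, 100))
}

# Truth-labelled rendered track populations for PID checks.
render_population <- function(n, mode, energy_range_kev, detector,
                              margin_px = 20) {
  lapply(seq_len(n), function(i) {
    em <- data.frame(
      mode = mode,
      energy_kev = runif(1, energy_range_kev[1L], energy_range_kev[2L]),
      x_px = runif(1, margin_px, 255 - margin_px),
      y_px = runif(1, margin_px, 255 - margin_px),
      time_ns = i * 1e5)
    render_track_hits(em, detector)
  })
}

# Wrap a list of per-track hit tables into a qpid_tracks object without
# running the clusterer (truth labels known by construction).
tracks_from_hit_list <- function(hit_list) {
  for (i in seq_along(hit_list)) hit_list[[i]]$track_id <- i
  hits <- do.call(rbind, hit_list)
  summ <- do.call(rbind, lapply(seq_along(hit_list), function(i) {
    s <- summarize_track(hit_list[[i]])
    data.frame(track_id = i, n_pixels = s$n_pixels,
               energy_kev = s$energy_kev, time_ns = s$time_ns,
               centroid_col = s$centroid["col"],
               centroid_row = s$centroid["row"])
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, hits = hits,
                 config = aggregation_config()),
            class = "qpid_tracks")
}

demo_scene <- function(activity_ra = 20, activity_f = 150,
                       duration_s = 2) {
  source_scene(rbind(point_source("Ra-223", 70, 70, activity_ra, 3),
                     point_source("F-18", 180, 180, activity_f, 3)),
               duration_s = duration_s)
}
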