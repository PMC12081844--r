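test_that("clustering follows the window-and-adjacency rule", {
  one <- pixel_hits(10, 10, 100, 50)
  expect_equal(nrow(build_tracks(one)$summary), 1L)

  pair_close <- pixel_hits(c(10, 11), c(10, 10), c(100, 110), c(50, 50))
  expect_equal(nrow(build_tracks(pair_close)$summary), 1L)

  pair_late <- pixel_hits(c(10, 11), c(10, 10), c(100, 200), c(50, 50))
  expect_equal(nrow(build_tracks(pair_late)$summary), 2L)

  pair_far <- pixel_hits(c(10, 20), c(10, 10), c(100, 110), c(50, 50))
  expect_equal(nrow(build_tracks(pair_far)$summary), 2L)

  # chain linking: consecutive links within the window may span > 40 ns
  chain <- pixel_hits(c(10, 11, 12), c(10, 10, 10), c(0, 35, 70),
                      c(10, 10, 10))
  expect_equal(nrow(build_tracks(chain)$summary), 1L)
})

test_that("uncalibrated hits are refused with a pointer to calibration", {
  raw <- pixel_hits(1, 1, 1, 100, calibrated = FALSE)
  expect_error(build_tracks(raw), "calibration")
})

test_that("partition matches the brute-force oracle on random fields", {
  set.seed(101)
  cfg <- aggregation_config()
  for (rep in 1:25) {
    n <- sample(20:220, 1)
    h <- random_hit_field(n)
    h$hit_id <- seq_len(n)
    got <- build_tracks(h, cfg)
    want <- oracle_partition(h, cfg$time_window_ns, cfg$radius_px)
    expect_true(same_partition(
      partition_sets(got$hits$hit_id, got$hits$track_id),
      partition_sets(seq_len(n), want)))
    # partition property and exact energy conservation
    expect_equal(sum(got$summary$n_pixels), n)
    expect_equal(sum(got$summary$energy_kev), sum(h$energy_kev))
  }
})

test_that("the partition is invariant under input permutation", {
  set.seed(55)
  h <- random_hit_field(150)
  h$hit_id <- 1:150
  a <- build_tracks(h)
  perm <- h[sample.int(150), ]
  class(perm) <- class(h); attr(perm, "calibrated") <- TRUE
  b <- build_tracks(perm)
  expect_true(same_partition(
    partition_sets(a$hits$hit_id, a$hits$track_id),
    partition_sets(b$hits$hit_id, b$hits$track_id)))
})

test_that("track summaries follow the energy/time/centroid definitions", {
  h <- data.frame(col = c(0L, 1L), row = c(0L, 0L),
                  toa_ns = c(10, 20), energy_kev = c(5, 5))
  s <- summarize_track(h)
  expect_equal(unname(s$centroid), c(0.5, 0))
  expect_equal(s$time_ns, 15)

  h2 <- data.frame(col = c(0L, 1L), row = c(0L, 0L),
                   toa_ns = c(0, 0), energy_kev = c(1, 3))
  expect_equal(unname(summarize_track(h2)$centroid[1]), 0.75)

  h3 <- data.frame(col = 1:3, row = rep(1L, 3), toa_ns = rep(0, 3),
                   energy_kev = c(100, 250, 4650))
  expect_equal(summarize_track(h3)$energy_kev, 5000)
  # centroid stays inside the pixel bounding box
  expect_true(summarize_track(h3)$centroid["col"] >= 1 &&
                summarize_track(h3)$centroid["col"] <= 3)
})

test_that("intra-track residual width recovers the configured jitter", {
  det <- detector_model()  # 7.7 ns intra-track FWHM target
  scene <- source_scene(point_source("F-18", 128, 128, 300, 4),
                        duration_s = 1)
  sim <- simulate_acquisition(scene, det, seed = 11)
  tr <- build_tracks(qpid:::strip_extra_cols(sim$hits))
  w <- hist_width(intra_track_time_residuals(tr))
  expect_lt(abs(w["fwhm"] - 7.7), 0.77)
  # degenerate case: identical times collapse to a delta at zero
  flat <- pixel_hits(c(5, 6, 5), c(5, 5, 6), rep(100, 3), c(1, 1, 1))
  res <- intra_track_time_residuals(build_tracks(flat))
  expect_equal(sum(res$counts > 0), 1L)
})

test_that("gaussian per-hit jitter reproduces the analytic FWHM", {
  set.seed(8)
  # single large synthetic track population with pure gaussian spread
  sigma <- 4
  hl <- lapply(1:4000, function(i) {
    n <- 4
    data.frame(col = (i %% 200) + c(0L, 1L, 0L, 1L),
               row = (i %/% 200) %% 200 + c(0L, 0L, 1L, 1L),
               toa_ns = i * 1e4 + rnorm(n, 0, sigma),
               energy_kev = rep(10, n), track_id = i)
  })
  tr <- tracks_from_hit_list(hl)
  w <- hist_width(intra_track_time_residuals(tr, bin_ns = 1))
  # mean-subtraction shrinks sigma by sqrt(1 - 1/n)
  expected <- 2 * sqrt(2 * log(2)) * sigma * sqrt(1 - 1 / 4)
  expect_lt(abs(w["fwhm"] - expected) / expected, 0.06)
})
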