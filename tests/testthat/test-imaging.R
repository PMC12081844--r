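track_fixture <- function() {
  hl <- list(
    data.frame(col = c(10L, 11L, 10L, 11L), row = c(10L, 10L, 11L, 11L),
               toa_ns = rep(100, 4), energy_kev = c(1000, 1000, 1500, 1500)),
    data.frame(col = 200L, row = 60L, toa_ns = 5000, energy_kev = 5000))
  tracks_from_hit_list(hl)
}

test_that("increment rules match the four mode x scale combinations", {
  tr <- track_fixture()
  em_act <- reconstruct_image(tr, "event_map", "activity", 10,
                              normalize = FALSE)
  expect_equal(em_act$grid[11, 11], 0.25)  # 4-pixel track: 1/N each
  expect_equal(sum(em_act$grid), 2)        # k tracks

  ce_act <- reconstruct_image(tr, "centroid", "activity", 10,
                              normalize = FALSE)
  expect_equal(sum(ce_act$grid), 2)
  expect_equal(ce_act$grid[61, 201], 1)    # centroid pixel of track 2

  em_sp <- reconstruct_image(tr, "event_map", "spectroscopic", 10,
                             normalize = FALSE)
  expect_equal(em_sp$grid[11, 11], 1000)
  expect_equal(sum(em_sp$grid), 10000)

  ce_sp <- reconstruct_image(tr, "centroid", "spectroscopic", 10,
                             normalize = FALSE)
  expect_equal(ce_sp$grid[61, 201], 5000)  # full track energy at centroid
  expect_equal(sum(ce_sp$grid), 10000)
})

test_that("normalization divides by time and, for spectroscopic, area", {
  tr <- track_fixture()
  im <- reconstruct_image(tr, "event_map", "activity", 10)
  expect_equal(sum(im$grid), 2 / 10)
  expect_equal(im$units, "events/s/pixel")
  sp <- reconstruct_image(tr, "centroid", "spectroscopic", 10)
  expect_equal(sum(sp$grid), 10000 / 1000 / 10 / (0.055^2))
  expect_equal(sp$units, "MeV/s/mm2")
})

test_that("conservation holds on a full synthetic run in both modes", {
  sim <- simulate_acquisition(demo_scene(duration_s = 1),
                              detector_model(), seed = 41)
  tr <- build_tracks(qpid:::strip_extra_cols(sim$hits))
  k <- nrow(tr$summary)
  e_tot <- sum(tr$summary$energy_kev)
  for (mode in c("event_map", "centroid")) {
    act <- reconstruct_image(tr, mode, "activity", 1, normalize = FALSE)
    expect_lt(abs(sum(act$grid) - k) / k, 1e-6)
    sp <- reconstruct_image(tr, mode, "spectroscopic", 1,
                            normalize = FALSE)
    expect_lt(abs(sum(sp$grid) - e_tot) / e_tot, 1e-6)
  }
})

test_that("activity scaling and cell-density conversion are linear", {
  tr <- track_fixture()
  im <- reconstruct_image(tr, "centroid", "activity", 10)
  bq <- to_activity_units(im, 2)
  expect_equal(sum(bq$grid), 2 * sum(im$grid))
  expect_equal(bq$units, "Bq/pixel")
  expect_error(to_activity_units(
    reconstruct_image(tr, "centroid", "spectroscopic", 10), 2),
    "activity")

  # 17.6 kBq per million cells; doubling thickness halves the density
  sa <- 17.6e3 / 1e6
  d10 <- to_cell_density(bq, sa, 10)
  d20 <- to_cell_density(bq, sa, 20)
  expect_equal(d10$grid, 2 * d20$grid)
  expect_equal(d10$units, "cells/uL")
  px_bq <- bq$grid[61, 201]
  vol_ul <- 0.055^2 * (10 / 1000)
  expect_equal(d10$grid[61, 201], px_bq / sa / vol_ul)
  expect_error(to_cell_density(bq, sa, 0), "thickness")
})

test_that("line profiles measure a planted Gaussian ridge at 180 um", {
  sigma_px <- 1.39  # 2 sqrt(2 log 2) * 1.39 px * 55 um = 180 um
  g <- matrix(0, 256, 256)
  for (r in 1:256)
    g[r, ] <- exp(-((1:256) - 128.5)^2 / (2 * sigma_px^2))
  im <- spectral_image(g, "centroid", "activity", "events/s/pixel", 1,
                       normalized = TRUE)
  p <- line_profile_fwhm(im, start = c(100, 127.5), end = c(155, 127.5))
  expect_lt(abs(p$fwhm_um - 180) / 180, 0.05)

  # single-pixel impulse: resolution floor of <= 2 pixels
  g2 <- matrix(0, 256, 256); g2[100, 100] <- 1
  im2 <- spectral_image(g2, "centroid", "activity", "x", 1)
  p2 <- line_profile_fwhm(im2, c(92, 99), c(106, 99), width_px = 1)
  expect_lte(p2$fwhm_um, 2 * 55)

  # constant stripe of width w: FWHM ~ w
  g3 <- matrix(0, 256, 256); g3[, 101:120] <- 1
  im3 <- spectral_image(g3, "centroid", "activity", "x", 1)
  p3 <- line_profile_fwhm(im3, c(80, 128), c(140, 128))
  expect_lt(abs(p3$fwhm_um - 20 * 55) / (20 * 55), 0.1)

  expect_error(line_profile_fwhm(
    spectral_image(matrix(1, 256, 256), "centroid", "activity", "x", 1),
    c(10, 10), c(50, 10)), "flat")
})

test_that("centroid images resolve point sources better than event maps", {
  det <- detector_model()
  scene <- source_scene(point_source("Th-227", 128, 128, 150, 0.8),
                        duration_s = 1)
  sim <- simulate_acquisition(scene, det, seed = 47)
  tr <- classify_tracks(build_tracks(qpid:::strip_extra_cols(sim$hits)))
  tr <- alpha_filter(tr)
  ce <- reconstruct_image(tr, "centroid", "activity", 1)
  em <- reconstruct_image(tr, "event_map", "activity", 1)
  p_ce <- line_profile_fwhm(ce, c(108, 128), c(148, 128), width_px = 20)
  p_em <- line_profile_fwhm(em, c(108, 128), c(148, 128), width_px = 20)
  expect_lt(p_ce$fwhm_um, p_em$fwhm_um)
})

test_that("ROI statistics recover planted levels and background", {
  g <- matrix(1, 256, 256)
  g[roi_rect(10, 29, 10, 29)] <- 5
  g[roi_rect(60, 79, 60, 79)] <- 3
  im <- spectral_image(g, "centroid", "activity", "x", 1)
  rois <- list(high = roi_rect(10, 29, 10, 29),
               low = roi_rect(60, 79, 60, 79),
               background = roi_rect(150, 169, 150, 169))
  st <- roi_statistics(im, rois)
  expect_equal(st$mean[st$label == "high"], 5)
  expect_equal(st$sem, rep(0, 3))
  expect_equal(st$mean_bg_sub[st$label == "high"], 4)
  expect_equal(st$mean_bg_sub[st$label == "low"], 2)
  expect_warning(
    roi_statistics(im, list(background = roi_rect(0, 20, 0, 20),
                            a = roi_rect(10, 30, 10, 30))),
    "overlaps")
})

test_that("dead-pixel masks divert centroids and zero event maps", {
  hl <- list(data.frame(col = c(50L, 51L), row = c(50L, 50L),
                        toa_ns = c(0, 0), energy_kev = c(5, 5)))
  tr <- tracks_from_hit_list(hl)  # centroid at (50.5, 50) -> pixel (50,50)
  mask <- data.frame(col = 50L, row = 50L)
  expect_message(
    ce <- reconstruct_image(tr, "centroid", "activity", 1,
                            normalize = FALSE, mask = mask),
    "moved")
  expect_equal(ce$grid[51, 51], 0)
  expect_equal(sum(ce$grid), 1)
  em <- reconstruct_image(tr, "event_map", "activity", 1,
                          normalize = FALSE, mask = mask)
  expect_equal(em$grid[51, 51], 0)
})
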