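test_that("decay counts are Poisson with mean activity x duration", {
  scene <- source_scene(point_source("F-18", 128, 128, 100, 2),
                        duration_s = 10)
  em <- sample_decays(scene, seed = 3)
  n <- length(unique(em$decay_id))
  expect_lt(abs(n - 1000), 4 * sqrt(1000))
})

test_that("Ra-223 scenes carry ~6 charged emissions per decay and mylar
           pulls alpha energies into the expected band", {
  scene <- source_scene(point_source("Ra-223", 100, 100, 60, 2),
                        duration_s = 5)
  em <- sample_decays(scene, seed = 4)
  per_decay <- nrow(em) / length(unique(em$decay_id))
  expect_lt(abs(per_decay - 6), 0.2)
  a <- em[em$mode == "alpha" & em$parent == "Ra-223", "energy_kev"]
  expect_true(all(a >= 5716 - 2000 & a <= 5716 - 1500))
})

test_that("zero-activity scenes give empty emission lists", {
  scene <- source_scene(point_source("F-18", 10, 10, 0), duration_s = 5)
  expect_equal(nrow(sample_decays(scene, seed = 1)), 0L)
})

test_that("hemisphere acceptance converges to 0.5", {
  f <- geometric_acceptance_fraction(1e6, seed = 11)
  expect_lt(abs(f - 0.5), 0.002)
  expect_equal(geometric_acceptance_fraction(1e4, seed = 1,
                                             force_sensorward = TRUE), 1)
})

test_that("alpha discs are wide, energy-conserving and time-quantized", {
  det <- detector_model()
  em <- data.frame(mode = "alpha", energy_kev = 5800, x_px = 128,
                   y_px = 128, time_ns = 5e4)
  h <- render_track_hits(em, det, seed = 21)
  expect_gte(nrow(h), 30)  # disc of diameter > 400 um at 55 um pitch
  expect_lt(abs(sum(h$energy_kev) - alpha_saturation(5800, det)), 0.1)
  expect_true(all(abs(h$toa_ns / 1.5625 - round(h$toa_ns / 1.5625))
                  < 1e-9))
})

test_that("low-energy Auger tracks stay within a few pixels", {
  det <- detector_model()
  em <- data.frame(mode = "auger", energy_kev = 12.7, x_px = 50,
                   y_px = 50, time_ns = 1e4)
  for (s in 1:5) {
    h <- render_track_hits(em, det, seed = s)
    expect_lte(nrow(h), 3)
    expect_lt(abs(sum(h$energy_kev) - 12.7), 0.1)
  }
})

test_that("beta path length grows with energy", {
  det <- detector_model()
  n_lo <- nrow(render_track_hits(
    data.frame(mode = "beta_minus", energy_kev = 50, x_px = 128,
               y_px = 128, time_ns = 0), det, seed = 5))
  n_hi <- nrow(render_track_hits(
    data.frame(mode = "beta_minus", energy_kev = 900, x_px = 128,
               y_px = 128, time_ns = 0), det, seed = 5))
  expect_gt(n_hi, n_lo)
  expect_gte(n_hi, 20)
})

test_that("gamma stream carries ~2.3% coincidences plus background", {
  det <- detector_model()
  em <- data.frame(decay_id = 1:10000, nuclide = "F-18",
                   parent = "F-18", mode = "beta_plus",
                   energy_kev = 250, x_px = 100, y_px = 100,
                   time_ns = seq_len(10000) * 1e5)
  g <- render_gamma_stream(em, det, duration_s = 1, seed = 9)
  expect_lt(abs(nrow(g) - 230), 60)  # 4 sigma of Poisson(230)
  expect_lt(abs(median(g$energy_kev) - 511), 15)
  # pulse area carries the inverse calibration constant
  expect_equal(g$energy_kev,
               gamma_energy_from_pulse_area(g$pulse_area,
                                            det$gamma_kev_per_pulse_unit))
  g0 <- render_gamma_stream(em[0, ], det, duration_s = 1, seed = 9)
  expect_equal(nrow(g0), 0L)
})

test_that("acquisitions are reproducible and internally consistent", {
  scene <- demo_scene(activity_ra = 15, activity_f = 60, duration_s = 1)
  det <- detector_model(gamma_background_bq = 3)
  sim1 <- simulate_acquisition(scene, det, seed = 31)
  sim2 <- simulate_acquisition(scene, det, seed = 31)
  expect_identical(sim1$hits, sim2$hits)
  expect_identical(sim1$gammas, sim2$gammas)
  expect_identical(sim1$truth, sim2$truth)
  # truth rows match rendered pixel counts
  expect_equal(sum(sim1$truth$n_pixels), nrow(sim1$hits))
  # an F-18-only scene yields only beta_plus truth rows
  f_only <- source_scene(point_source("F-18", 100, 100, 80),
                         duration_s = 1)
  simf <- simulate_acquisition(f_only, det, seed = 32)
  expect_setequal(unique(simf$truth$mode), "beta_plus")
  # mixed scene has both alpha and beta_plus truth rows
  expect_true(all(c("alpha", "beta_plus") %in% sim1$truth$mode))
})

test_that("written acquisition files are byte-identical under one seed", {
  scene <- source_scene(point_source("F-18", 100, 100, 40),
                        duration_s = 1)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_acquisition(scene, seed = 77, out_dir = d1)
  simulate_acquisition(scene, seed = 77, out_dir = d2)
  for (f in c("pixels.tsv", "gammas.tsv", "truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))))
  }
  # and the pixel file is valid v1 dialect
  expect_s3_class(read_listmode(file.path(d1, "pixels.tsv"), "pixel"),
                  "qpid_hits")
})
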