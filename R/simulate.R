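# Synthetic-source simulator: decay sampling, detector response, and
# list-mode stream generation.  This is a statistical surrogate for the
# hardware, not a transport Monte Carlo: track morphologies, timing
# spreads and the mylar energy loss are drawn from simple parametric
# models whose scales are set to the detector's measured figures.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation, kept below 2^31.
sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 2011L + k

#' Planar source scene
#'
#' Describes the radioactive sample resting on the detector: one or more
#' point-drop sources (each a 2-d Gaussian activity footprint), the
#' sample thickness, the mylar energy-loss model for alphas, and the
#' acquisition duration.
#'
#' @param sources data frame from [point_source()] (rows may be
#'   concatenated with `rbind`): columns `nuclide`, `x_px`, `y_px`,
#'   `sigma_px`, `activity_bq`.
#' @param duration_s acquisition duration in seconds.
#' @param thickness_um sample thickness in micrometres.
#' @param mylar_loss_kev two-element range of the alpha energy absorbed
#'   by the protective mylar film, keV; each alpha loses a uniform draw
#'   from this range before detection.  Default 1500-2000 keV.
#' @param t0_ns stream start time offset, ns.
#' @param daughter_timing `"prompt"`: every chain daughter decays at the
#'   parent decay time (adequate for images and truth accounting, but
#'   chain members pile up into one cluster); `"equilibrium"`: each
#'   emission gets an independent uniform time over the acquisition,
#'   the behaviour of a source in secular equilibrium whose daughter
#'   half-lives dwarf the clustering window.
#' @return An object of class `source_scene`.
#' @export
source_scene <- function(sources, duration_s, thickness_um = 10,
                         mylar_loss_kev = c(1500, 2000), t0_ns = 1000,
                         daughter_timing = c("equilibrium", "prompt")) {
  daughter_timing <- match.arg(daughter_timing)
  stopifnot(is.data.frame(sources), nrow(sources) >= 0,
            all(c("nuclide", "x_px", "y_px", "sigma_px", "activity_bq")
                %in% names(sources)))
  if (any(sources$activity_bq < 0)) stop("activities must be >= 0")
  if (duration_s <= 0) stop("duration must be > 0")
  if (thickness_um <= 0) stop("thickness must be > 0")
  structure(list(sources = sources, duration_s = duration_s,
                 thickness_um = thickness_um,
                 mylar_loss_kev = sort(mylar_loss_kev), t0_ns = t0_ns,
                 daughter_timing = daughter_timing),
            class = "source_scene")
}

#' @rdname source_scene
#' @param nuclide chain name understood by [nuclide_chain()].
#' @param x_px,y_px drop centre in fractional pixel coordinates.
#' @param activity_bq source activity in Bq.
#' @param sigma_px Gaussian footprint of the dried drop, pixels.
#' @export
point_source <- function(nuclide, x_px, y_px, activity_bq, sigma_px = 2) {
  data.frame(nuclide = nuclide, x_px = x_px, y_px = y_px,
             sigma_px = sigma_px, activity_bq = activity_bq,
             stringsAsFactors = FALSE)
}

#' Detector response model
#'
#' Parameters of the synthetic detector response.  Timing scales are
#' specified as target FWHMs; the underlying draw scales are derived from
#' them (the intra-track jitter uses a right-skewed
#' exponentially-modified-Gaussian so the residual histogram is
#' asymmetric, the coincidence jitter is Gaussian).
#'
#' @param track_fwhm_ns target FWHM of the intra-track time-residual
#'   histogram, ns (default 7.7).
#' @param track_tail_ratio exponential-tail-to-Gaussian ratio tau/sigma
#'   of the intra-track jitter (default 1: visibly skewed).
#' @param ctr_fwhm_ns target FWHM of the track-gamma coincidence timing
#'   distribution, ns (default 24.2).
#' @param alpha_diameter_um mean alpha track diameter, micrometres
#'   (default 450, i.e. over 400 um).
#' @param alpha_diameter_sd_um sd of the alpha diameter draw.
#' @param beta_range_k,beta_range_p beta path-length surrogate
#'   `L = round(k * E^p)` pixels for energy E in keV; defaults give
#'   ~1 pixel at 12.7 keV and ~40 pixels at 900 keV.
#' @param gamma_coinc_prob probability that a beta-plus emission yields a
#'   detected coincident 511 keV gamma (default 0.023).
#' @param gamma_sigma_kev Gaussian energy resolution of the gamma channel.
#' @param gamma_background_bq rate of uncorrelated background singles, Bq.
#' @param gamma_bg_range_kev energy range of background singles, keV.
#' @param gamma_kev_per_pulse_unit calibration constant relating gamma
#'   pulse area to energy; the simulator writes
#'   `pulse_area = energy / constant`.
#' @param alpha_sat_knee_kev,alpha_sat_slope saturation model for the
#'   measured alpha energy: below the knee the response is linear, above
#'   it the detector reports `knee + slope * (E - knee)` with slope < 1,
#'   emulating the high-LET under-response that the secondary alpha
#'   calibration must undo.  Defaults: knee 3000 keV, slope 0.72.
#' @param pixel_energy_sigma fractional per-pixel energy noise.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(track_fwhm_ns = 7.7, track_tail_ratio = 1,
                           ctr_fwhm_ns = 24.2,
                           alpha_diameter_um = 450,
                           alpha_diameter_sd_um = 40,
                           beta_range_k = 0.11, beta_range_p = 0.87,
                           gamma_coinc_prob = 0.023,
                           gamma_sigma_kev = 20,
                           gamma_background_bq = 0,
                           gamma_bg_range_kev = c(100, 1400),
                           gamma_kev_per_pulse_unit = 0.5,
                           alpha_sat_knee_kev = 3000,
                           alpha_sat_slope = 0.72,
                           pixel_energy_sigma = 0.0) {
  stopifnot(track_fwhm_ns > 0, ctr_fwhm_ns > 0,
            gamma_coinc_prob >= 0, gamma_coinc_prob <= 1,
            alpha_diameter_um > 0, beta_range_k > 0)
  structure(list(
    track_fwhm_ns = track_fwhm_ns, track_tail_ratio = track_tail_ratio,
    track_sigma_ns = track_fwhm_ns / emg_fwhm_unit(track_tail_ratio),
    ctr_fwhm_ns = ctr_fwhm_ns, ctr_sigma_ns = ctr_fwhm_ns / GAUSS_FWHM,
    alpha_diameter_um = alpha_diameter_um,
    alpha_diameter_sd_um = alpha_diameter_sd_um,
    beta_range_k = beta_range_k, beta_range_p = beta_range_p,
    gamma_coinc_prob = gamma_coinc_prob,
    gamma_sigma_kev = gamma_sigma_kev,
    gamma_background_bq = gamma_background_bq,
    gamma_bg_range_kev = gamma_bg_range_kev,
    gamma_kev_per_pulse_unit = gamma_kev_per_pulse_unit,
    alpha_sat_knee_kev = alpha_sat_knee_kev,
    alpha_sat_slope = alpha_sat_slope,
    pixel_energy_sigma = pixel_energy_sigma),
    class = "detector_model")
}

# FWHM of an exponentially-modified Gaussian with sigma = 1, tau = ratio,
# computed numerically from the closed-form density.  FWHM scales
# linearly with sigma at fixed ratio, so one evaluation calibrates the
# jitter scale for any target FWHM.
emg_fwhm_unit <- function(ratio) {
  if (ratio <= 1e-8) return(GAUSS_FWHM)
  erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
  dens <- function(x)
    1 / (2 * ratio) * exp(1 / (2 * ratio^2) - x / ratio) *
      erfc((1 / ratio - x) / sqrt(2))
  x <- seq(-8, 8 + 12 * ratio, by = 1e-3)
  y <- dens(x)
  half <- max(y) / 2
  above <- which(y >= half)
  i <- above[1L]; j <- above[length(above)]
  xl <- stats::approx(y[c(i - 1L, i)], x[c(i - 1L, i)], xout = half)$y
  xr <- stats::approx(y[c(j + 1L, j)], x[c(j + 1L, j)], xout = half)$y
  xr - xl
}

# Draw n intra-track jitters (ns): centred EMG with the detector's scale.
draw_track_jitter <- function(n, detector) {
  s <- detector$track_sigma_ns
  tau <- detector$track_tail_ratio * s
  stats::rnorm(n, 0, s) + stats::rexp(n, 1 / max(tau, 1e-12)) - tau
}

quantize_time <- function(t_ns) {
  pmax(round(t_ns / QPID_TIME_QUANTUM_NS) * QPID_TIME_QUANTUM_NS, 0)
}

#' Hemisphere acceptance of a surface source
#'
#' Fraction of isotropically sampled emission directions from a point
#' source resting on the sensor plane that enter the sensor-side
#' hemisphere.  Converges to 0.5 (the 2-pi solid-angle acceptance) with
#' Monte Carlo error ~ n^-1/2.
#'
#' @param n_samples number of sampled directions.
#' @param seed optional RNG seed.
#' @param force_sensorward if `TRUE` every direction is reflected into the
#'   sensor-side hemisphere (degenerate check: the fraction is then 1).
#' @return Scalar acceptance fraction.
#' @export
geometric_acceptance_fraction <- function(n_samples, seed = NULL,
                                          force_sensorward = FALSE) {
  stopifnot(n_samples >= 1)
  with_seed(seed, {
    cz <- stats::runif(n_samples, -1, 1)  # isotropic: cos(theta) uniform
    if (force_sensorward) cz <- -abs(cz)
    mean(cz < 0)
  })
}

#' Expected charged-particle detections per decay
#'
#' Simulates `n_decays` decays of a chain, emits every charged particle
#' along the chain isotropically, and counts those entering the
#' sensor-side hemisphere.  For Ra-223 (6 charged emissions per decay)
#' the expectation is 3 detections per decay.
#'
#' @param chain a `nuclide_chain`.
#' @param n_decays number of simulated parent decays.
#' @param seed optional RNG seed.
#' @return Mean number of hemisphere-entering charged emissions per decay.
#' @export
charged_detections_per_decay <- function(chain, n_decays, seed = NULL) {
  stopifnot(inherits(chain, "nuclide_chain"), n_decays >= 1)
  with_seed(seed, {
    if (all(abs(chain$branching - 1) < 1e-12)) {
      # deterministic chain: every decay emits the full path
      n_em <- rep.int(length(walk_chain_idx(chain)), n_decays)
    } else {
      n_em <- vapply(seq_len(n_decays),
                     function(i) length(walk_chain_idx(chain)),
                     integer(1))
    }
    total <- sum(n_em)
    accepted <- sum(stats::runif(total, -1, 1) < 0)
    accepted / n_decays
  })
}

# One random walk through a chain: returns the indices of the realized
# step rows (branches sampled with their fractions).
walk_chain_idx <- function(chain) {
  cur <- attr(chain, "head")
  idx <- integer(0)
  repeat {
    rows <- which(chain$parent == cur)
    if (!length(rows)) break
    k <- if (length(rows) == 1L) rows else
      sample(rows, 1L, prob = chain$branching[rows])
    idx <- c(idx, k)
    cur <- chain$daughter[k]
    if (length(idx) > nrow(chain)) stop("chain walk did not terminate")
  }
  idx
}

walk_chain <- function(chain) chain[walk_chain_idx(chain), , drop = FALSE]

#' Sample decays and emissions for a scene
#'
#' Draws Poisson decay counts for every source (`activity x duration`),
#' uniform decay times over the acquisition, Gaussian drop positions,
#' walks the decay chain of each decay (daughter emission times per the
#' scene's `daughter_timing`), samples emission energies, and subtracts
#' the mylar energy loss from alpha emissions.
#'
#' @param scene a [source_scene()].
#' @param seed optional RNG seed.
#' @return Data frame of emissions: `decay_id`, `nuclide` (chain head),
#'   `parent` (emitting nuclide), `mode`, `energy_kev` (post-mylar for
#'   alphas), `x_px`, `y_px`, `time_ns`.
#' @export
sample_decays <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "source_scene"))
  with_seed(seed, {
    out <- list(); id0 <- 0L
    for (s in seq_len(nrow(scene$sources))) {
      src <- scene$sources[s, ]
      chain <- nuclide_chain(src$nuclide)
      n <- stats::rpois(1L, src$activity_bq * scene$duration_s)
      if (n == 0L) next
      t_dec <- scene$t0_ns + sort(stats::runif(n)) * scene$duration_s * 1e9
      xs <- stats::rnorm(n, src$x_px, src$sigma_px)
      ys <- stats::rnorm(n, src$y_px, src$sigma_px)
      xs <- pmin(pmax(xs, 0), QPID_GRID - 1e-6)
      ys <- pmin(pmax(ys, 0), QPID_GRID - 1e-6)
      for (i in seq_len(n)) {
        steps <- walk_chain(chain)
        if (!nrow(steps)) next
        e <- vapply(seq_len(nrow(steps)),
                    function(k) sample_step_energy(steps[k, ]), numeric(1))
        is_a <- steps$mode == "alpha"
        if (any(is_a))
          e[is_a] <- e[is_a] - stats::runif(sum(is_a),
                                            scene$mylar_loss_kev[1L],
                                            scene$mylar_loss_kev[2L])
        t_em <- if (scene$daughter_timing == "prompt" ||
                      nrow(steps) == 1L) rep(t_dec[i], nrow(steps))
                else scene$t0_ns +
                  stats::runif(nrow(steps)) * scene$duration_s * 1e9
        out[[length(out) + 1L]] <- data.frame(
          decay_id = id0 + i, nuclide = src$nuclide,
          parent = steps$parent, mode = steps$mode, energy_kev = e,
          x_px = xs[i], y_px = ys[i], time_ns = t_em,
          stringsAsFactors = FALSE)
      }
      id0 <- id0 + n
    }
    if (!length(out))
      return(data.frame(decay_id = integer(), nuclide = character(),
                        parent = character(), mode = character(),
                        energy_kev = numeric(), x_px = numeric(),
                        y_px = numeric(), time_ns = numeric(),
                        stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Render the pixel hits of one emission
#'
#' Alpha (and other high-LET) emissions become filled discs of pixels
#' with a truncated-Gaussian radial energy profile; betas and Augers
#' become self-avoiding random-walk pixel chains whose length grows with
#' energy.  Pixel energies sum to the recorded track energy (the absorbed
#' energy, compressed by [alpha_saturation()] for alphas); hit times
#' are the emission time plus per-hit jitter, quantized to the 1.5625 ns
#' sampling quantum.
#'
#' @param emission one-row data frame (or list) with `mode`,
#'   `energy_kev`, `x_px`, `y_px`, `time_ns`.
#' @param detector a [detector_model()].
#' @param seed optional RNG seed.
#' @return A `qpid_hits` data frame (calibrated energies, keV).
#' @export
render_track_hits <- function(emission, detector, seed = NULL) {
  with_seed(seed, {
    e <- emission$energy_kev
    if (e <= 0) stop("emission energy must be positive", call. = FALSE)
    cx <- emission$x_px; cy <- emission$y_px
    if (emission$mode == "alpha") {
      # high-LET saturation: the recorded track energy is compressed
      # above the knee; the secondary alpha calibration undoes this.
      e <- alpha_saturation(e, detector)
      d_um <- stats::rnorm(1, detector$alpha_diameter_um,
                           detector$alpha_diameter_sd_um)
      d_um <- max(d_um, 3 * QPID_PITCH_UM)
      r_px <- d_um / 2 / QPID_PITCH_UM
      ir <- ceiling(r_px)
      cand <- expand.grid(col = floor(cx) + (-ir:ir),
                          row = floor(cy) + (-ir:ir))
      dd <- sqrt((cand$col + 0.5 - cx)^2 + (cand$row + 0.5 - cy)^2)
      keep <- dd <= r_px & cand$col >= 0 & cand$col <= 255 &
        cand$row >= 0 & cand$row <= 255
      cand <- cand[keep, , drop = FALSE]; dd <- dd[keep]
      if (!nrow(cand)) {  # off-grid clip: deposit at the nearest pixel
        cand <- data.frame(col = min(max(floor(cx), 0), 255),
                           row = min(max(floor(cy), 0), 255))
        dd <- 0
      }
      w <- exp(-dd^2 / (2 * (r_px / 2)^2))
      px <- cand
    } else {
      len <- max(1L, as.integer(round(
        detector$beta_range_k * e^detector$beta_range_p)))
      px <- self_avoiding_walk(floor(cx), floor(cy), len)
      w <- stats::runif(nrow(px), 0.5, 1.5)
    }
    if (detector$pixel_energy_sigma > 0)
      w <- w * pmax(stats::rnorm(nrow(px), 1, detector$pixel_energy_sigma),
                    0.05)
    en <- w / sum(w) * e
    t <- quantize_time(emission$time_ns +
                         draw_track_jitter(nrow(px), detector))
    pixel_hits(px$col, px$row, t, en)
  })
}

# Persistent self-avoiding 8-neighbour lattice walk of (up to) n pixels:
# the walker keeps its heading with probability `persist` and otherwise
# scatters to a random direction, giving the characteristic
# "linear with kinks" beta track morphology.  Clipped to the grid;
# stops early if boxed in.
self_avoiding_walk <- function(c0, r0, n, persist = 0.95) {
  c0 <- min(max(c0, 0L), 255L); r0 <- min(max(r0, 0L), 255L)
  cols <- integer(n); rows <- integer(n)
  cols[1L] <- c0; rows[1L] <- r0
  seen <- new.env(hash = TRUE, size = 2L * n)
  assign(paste(c0, r0), TRUE, envir = seen)
  # compass order: consecutive indices differ by 45 degrees
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dir <- sample.int(8L, 1L)
  k <- 1L
  while (k < n) {
    if (stats::runif(1) > persist) dir <- sample.int(8L, 1L)
    # try headings by angular distance from the current one
    dist <- pmin((seq_len(8L) - dir) %% 8L, (dir - seq_len(8L)) %% 8L)
    ord <- order(dist + stats::runif(8L) * 0.5)
    moved <- FALSE
    for (m in ord) {
      nc <- cols[k] + dc[m]; nr <- rows[k] + dr[m]
      if (nc < 0L || nc > 255L || nr < 0L || nr > 255L) next
      key <- paste(nc, nr)
      if (!is.null(seen[[key]])) next
      k <- k + 1L
      cols[k] <- nc; rows[k] <- nr
      assign(key, TRUE, envir = seen)
      dir <- m
      moved <- TRUE
      break
    }
    if (!moved) break
  }
  data.frame(col = cols[seq_len(k)], row = rows[seq_len(k)])
}

#' Render the gamma list-mode stream
#'
#' Each beta-plus emission yields, with the detector's coincidence
#' detection probability, a 511 keV annihilation gamma at the emission
#' time plus Gaussian coincidence-timing jitter; uncorrelated background
#' singles are added as a Poisson stream over the acquisition.
#'
#' @param emissions emission table from [sample_decays()].
#' @param detector a [detector_model()].
#' @param duration_s acquisition duration (for the background stream).
#' @param t0_ns stream start offset, ns.
#' @param seed optional RNG seed.
#' @return A `qpid_gammas` data frame with calibrated energies and the
#'   corresponding raw pulse areas.
#' @export
render_gamma_stream <- function(emissions, detector, duration_s,
                                t0_ns = 0, seed = NULL) {
  with_seed(seed, {
    bp <- emissions[emissions$mode == "beta_plus", , drop = FALSE]
    keep <- if (nrow(bp)) stats::runif(nrow(bp)) < detector$gamma_coinc_prob
            else logical(0)
    bp <- bp[keep, , drop = FALSE]
    t <- numeric(0); en <- numeric(0)
    if (nrow(bp)) {
      t <- bp$time_ns + stats::rnorm(nrow(bp), 0, detector$ctr_sigma_ns)
      en <- pmax(stats::rnorm(nrow(bp), 511, detector$gamma_sigma_kev), 1)
    }
    n_bg <- stats::rpois(1L, detector$gamma_background_bq * duration_s)
    if (n_bg > 0) {
      t <- c(t, t0_ns + stats::runif(n_bg) * duration_s * 1e9)
      en <- c(en, stats::runif(n_bg, detector$gamma_bg_range_kev[1L],
                               detector$gamma_bg_range_kev[2L]))
    }
    o <- order(t)
    gamma_events(pmax(t[o], 0), en[o] / detector$gamma_kev_per_pulse_unit,
                 en[o])
  })
}

#' End-to-end synthetic acquisition
#'
#' Samples decays for the scene, applies the hemisphere acceptance to
#' charged emissions, renders each accepted emission into pixel hits and
#' the beta-plus population into the gamma stream, and returns the two
#' list-mode streams together with a per-emission truth table.  With
#' `out_dir` set, writes `pixels.tsv`, `gammas.tsv` (v1 dialect) and
#' `truth.tsv`; byte-identical for a fixed seed.
#'
#' @param scene a [source_scene()].
#' @param detector a [detector_model()].
#' @param seed RNG seed (required: acquisitions are reproducible).
#' @param out_dir optional output directory.
#' @param apply_acceptance subject charged emissions to the 0.5
#'   hemisphere acceptance (default `TRUE`).
#' @return List with `hits` (`qpid_hits`), `gammas` (`qpid_gammas`) and
#'   `truth` (data frame: `emission_id`, `nuclide`, `parent`, `mode`,
#'   `energy_kev`, `x_px`, `y_px`, `time_ns`, `n_pixels`).
#' @export
simulate_acquisition <- function(scene, detector = detector_model(),
                                 seed, out_dir = NULL,
                                 apply_acceptance = TRUE) {
  if (anyDuplicated(paste(scene$sources$nuclide, scene$sources$x_px,
                          scene$sources$y_px)))
    stop("conflicting duplicate sources in scene", call. = FALSE)
  emissions <- sample_decays(scene, seed = sub_seed(seed, 1L))
  hit_list <- list(); truth <- list()
  with_seed(sub_seed(seed, 2L), {
    if (nrow(emissions)) {
      if (apply_acceptance) {
        acc <- stats::runif(nrow(emissions), -1, 1) < 0
        charged <- emissions$mode %in%
          c("alpha", "beta_minus", "beta_plus", "auger")
        emissions <- emissions[acc | !charged, , drop = FALSE]
      }
      # beta-plus annihilation gammas are emitted regardless of whether
      # the positron track itself landed on the sensor; keep the full
      # emission table for the gamma stage via attribute below.
      for (i in seq_len(nrow(emissions))) {
        h <- render_track_hits(emissions[i, ], detector)
        h$emission_id <- i
        hit_list[[i]] <- h
        truth[[i]] <- data.frame(
          emission_id = i, nuclide = emissions$nuclide[i],
          parent = emissions$parent[i], mode = emissions$mode[i],
          energy_kev = emissions$energy_kev[i],
          x_px = emissions$x_px[i], y_px = emissions$y_px[i],
          time_ns = emissions$time_ns[i], n_pixels = nrow(h),
          stringsAsFactors = FALSE)
      }
    }
  })
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    cbind(pixel_hits(), emission_id = integer())
  o <- order(hits$toa_ns)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "calibrated") <- TRUE
  class(hits) <- c("qpid_hits", "data.frame")
  gammas <- render_gamma_stream(emissions, detector, scene$duration_s,
                                t0_ns = scene$t0_ns,
                                seed = sub_seed(seed, 3L))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(emission_id = integer(), nuclide = character(),
               parent = character(), mode = character(),
               energy_kev = numeric(), x_px = numeric(), y_px = numeric(),
               time_ns = numeric(), n_pixels = integer(),
               stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_listmode(strip_extra_cols(hits), file.path(out_dir, "pixels.tsv"))
    write_listmode(gammas, file.path(out_dir, "gammas.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(hits = hits, gammas = gammas, truth = truth)
}

strip_extra_cols <- function(hits) {
  out <- hits[, c("col", "row", "toa_ns", "energy_kev")]
  attr(out, "calibrated") <- is_calibrated(hits)
  class(out) <- c("qpid_hits", "data.frame")
  out
}
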