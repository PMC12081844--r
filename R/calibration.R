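#' Pixel energy calibration (ToT to keV)
#'
#' Surrogate for the factory calibration that converts the per-pixel
#' time-over-threshold measurement to deposited energy: a global affine
#' map `energy = slope * ToT + intercept`, optionally overridden per
#' pixel by a table of coefficients.
#'
#' @param slope,intercept global affine coefficients (slope > 0).
#' @param per_pixel optional data frame `col`, `row`, `slope`,
#'   `intercept` of per-pixel coefficients.
#' @param global_fallback when a pixel is missing from `per_pixel`, fall
#'   back to the global map (`TRUE`) or raise an error (`FALSE`).
#' @return A `pixel_calibration` object.
#' @export
pixel_calibration <- function(slope = 1, intercept = 0, per_pixel = NULL,
                              global_fallback = TRUE) {
  stopifnot(slope > 0)
  if (!is.null(per_pixel)) {
    stopifnot(all(c("col", "row", "slope", "intercept") %in%
                    names(per_pixel)),
              all(per_pixel$slope > 0))
  }
  structure(list(slope = slope, intercept = intercept,
                 per_pixel = per_pixel,
                 global_fallback = isTRUE(global_fallback)),
            class = "pixel_calibration")
}

#' Apply the pixel energy calibration to a raw hit stream
#'
#' Replaces the raw ToT values of an uncalibrated stream with keV and
#' flips the `calibrated` flag.  Calling it on an already-calibrated
#' stream is a warning no-op.
#'
#' @param hits a `qpid_hits` data frame.
#' @param cal a [pixel_calibration()].
#' @return The calibrated `qpid_hits`.
#' @export
apply_pixel_energy_calibration <- function(hits, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  if (is_calibrated(hits)) {
    warning("hits are already calibrated; returning unchanged")
    return(hits)
  }
  slope <- rep(cal$slope, nrow(hits))
  icpt <- rep(cal$intercept, nrow(hits))
  if (!is.null(cal$per_pixel)) {
    key <- paste(hits$col, hits$row)
    i <- match(key, paste(cal$per_pixel$col, cal$per_pixel$row))
    missing <- is.na(i)
    if (any(missing) && !cal$global_fallback)
      stop("pixel(s) missing from calibration table: ",
           paste(utils::head(unique(key[missing]), 5), collapse = "; "),
           call. = FALSE)
    slope[!missing] <- cal$per_pixel$slope[i[!missing]]
    icpt[!missing] <- cal$per_pixel$intercept[i[!missing]]
  }
  hits$energy_kev <- slope * hits$energy_kev + icpt
  validate_pixel_hits(hits, calibrated = TRUE)
  attr(hits, "calibrated") <- TRUE
  hits
}

#' Secondary alpha energy transformation
#'
#' The factory ToT calibration under-reports alpha energies (high-LET
#' saturation of the silicon response) and the protective mylar film
#' absorbs 1.5-2 MeV more; `fit_alpha_transform` builds the monotone
#' piecewise-linear map from measured alpha peak positions to
#' alpha-spectrometer reference energies that undoes both.  Evaluation
#' outside the calibration span extrapolates linearly along the end
#' segments.
#'
#' @param measured_peaks strictly increasing peak positions measured on
#'   the pixel detector, keV.
#' @param reference_peaks matching strictly increasing reference line
#'   energies, keV (e.g. Pu-239 5144, Am-241 5485, Cm-244 5804).
#' @return An `alpha_transform` object; use [apply_alpha_transform()] or
#'   `predict()` to evaluate it.
#' @examples
#' tr <- fit_alpha_transform(c(4000, 4300, 4600), c(5144, 5485, 5804))
#' predict(tr, 4300)  # 5485
#' @export
fit_alpha_transform <- function(measured_peaks, reference_peaks) {
  m <- as.numeric(measured_peaks); r <- as.numeric(reference_peaks)
  if (length(m) != length(r) || length(m) < 2L)
    stop("need >= 2 matched peak pairs", call. = FALSE)
  if (any(diff(m) <= 0) || any(diff(r) <= 0))
    stop("peak lists must be strictly increasing (transform must be invertible)",
         call. = FALSE)
  structure(list(measured = m, reference = r), class = "alpha_transform")
}

#' @export
predict.alpha_transform <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  m <- object$measured; r <- object$reference
  y <- stats::approx(m, r, xout = x, rule = 1)$y
  k <- length(m)
  lo <- x < m[1L]
  hi <- x > m[k]
  if (any(lo)) {
    s <- (r[2L] - r[1L]) / (m[2L] - m[1L])
    y[lo] <- r[1L] + s * (x[lo] - m[1L])
  }
  if (any(hi)) {
    s <- (r[k] - r[k - 1L]) / (m[k] - m[k - 1L])
    y[hi] <- r[k] + s * (x[hi] - m[k])
  }
  y
}

#' @export
print.alpha_transform <- function(x, ...) {
  cat("alpha energy transform through", length(x$measured),
      "peak pairs:\n")
  print(data.frame(measured_kev = x$measured,
                   reference_kev = x$reference))
  invisible(x)
}

#' @rdname fit_alpha_transform
#' @param track_energy numeric vector of measured alpha track energies,
#'   keV.
#' @param transform an `alpha_transform`.
#' @param pid optional particle labels for `track_energy`; the transform
#'   applies only to alpha tracks, so any `"beta"` label is a contract
#'   violation.
#' @export
apply_alpha_transform <- function(track_energy, transform, pid = NULL) {
  stopifnot(inherits(transform, "alpha_transform"))
  if (!is.null(pid) && any(pid == "beta"))
    stop("alpha transform applied to beta-labelled track(s)",
         call. = FALSE)
  predict(transform, track_energy)
}

#' Gamma energy from pulse area
#'
#' The scintillator channel is calibrated with a single constant,
#' `energy = constant * pulse_area`, with the constant chosen so the
#' annihilation photopeak sits at 511 keV.
#'
#' @param pulse_area digitizer pulse area, arbitrary units.
#' @param constant keV per pulse-area unit (> 0).
#' @return Energy in keV.
#' @export
gamma_energy_from_pulse_area <- function(pulse_area, constant) {
  stopifnot(constant > 0)
  constant * pulse_area
}

#' Simulated measured alpha-line spectrum
#'
#' Draws `n_events` alphas of a nominal line energy through the mylar
#' energy-loss and saturation models and bins the measured energies:
#' the raw material for fitting and validating the secondary alpha
#' transform without hardware.
#'
#' @param line_kev nominal alpha line energy, keV.
#' @param n_events number of detected alphas.
#' @param detector a [detector_model()] (saturation parameters).
#' @param mylar_loss_kev uniform energy-loss range, keV.
#' @param bin_kev histogram bin width, keV.
#' @param seed optional RNG seed.
#' @return An `energy_spectrum` of measured energies.
#' @export
simulate_alpha_spectrum <- function(line_kev, n_events,
                                    detector = detector_model(),
                                    mylar_loss_kev = c(1500, 2000),
                                    bin_kev = 25, seed = NULL) {
  stopifnot(n_events >= 1)
  with_seed(seed, {
    absorbed <- line_kev - stats::runif(n_events, mylar_loss_kev[1L],
                                        mylar_loss_kev[2L])
    bin_spectrum(alpha_saturation(absorbed, detector), bin_kev)
  })
}

#' Simulated detector response to an alpha energy
#'
#' The measured-energy model the secondary alpha calibration must undo:
#' linear below the saturation knee, compressed by the saturation slope
#' above it.  (Mylar loss is applied upstream in [sample_decays()].)
#'
#' @param e_kev absorbed alpha energy in silicon, keV.
#' @param detector a [detector_model()].
#' @return Measured energy, keV.
#' @export
alpha_saturation <- function(e_kev, detector = detector_model()) {
  knee <- detector$alpha_sat_knee_kev
  ifelse(e_kev <= knee, e_kev,
         knee + detector$alpha_sat_slope * (e_kev - knee))
}
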