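#' Spectral deconvolution of a multi-isotope energy spectrum
#'
#' Models the measured spectrum as a linear sum of unit-normalized
#' per-isotope basis spectra, `S_i = sum_j A_j phi_ij`, and finds the
#' amplitudes `A_j` minimizing the unweighted sum of squares
#' `sum_i (S_i - sum_j A_j phi_ij)^2`, by default under the physical
#' constraint `A_j >= 0` (a small Lawson-Hanson active-set solver).
#' When the unconstrained least-squares solution is already
#' non-negative the two routes coincide.  Amplitude uncertainties
#' account for the Poisson bin variances of counting data: the
#' covariance is the sandwich form
#' `(Phi'Phi)^-1 Phi' V Phi (Phi'Phi)^-1` with `V = diag(fitted)`
#' (for the Poisson-weighted fit it reduces to `(Phi' V^-1 Phi)^-1`).
#'
#' @param data_spectrum an `energy_spectrum` of the measured counts.
#' @param bases named list of basis `energy_spectrum`s on the same bin
#'   edges; normalized to unit sum if not already.
#' @param nonneg constrain amplitudes to be non-negative (default
#'   `TRUE`).
#' @param weighted if `TRUE`, weight each bin by the inverse of its
#'   (estimated Poisson) variance instead of the plain sum of squares;
#'   off by default so the unweighted formulation is the reference
#'   behaviour.
#' @return An object of class `qpid_deconv` with methods `print`,
#'   `summary`, `coef`, `vcov`, `fitted`, `residuals`.
#' @examples
#' e <- seq(0, 100, by = 10)
#' b1 <- normalize_basis(energy_spectrum(e, c(5, 9, 5, 1, 0, 0, 0, 0, 0, 0)))
#' b2 <- normalize_basis(energy_spectrum(e, c(0, 0, 0, 1, 5, 9, 5, 1, 0, 0)))
#' s <- energy_spectrum(e, 2 * b1$counts + 3 * b2$counts)
#' coef(deconvolve_activities(s, list(x = b1, y = b2)))  # 2, 3
#' @export
deconvolve_activities <- function(data_spectrum, bases, nonneg = TRUE,
                                  weighted = FALSE) {
  stopifnot(inherits(data_spectrum, "energy_spectrum"),
            is.list(bases), length(bases) >= 1)
  bases <- lapply(bases, function(b) {
    stopifnot(inherits(b, "energy_spectrum"))
    if (!isTRUE(all.equal(b$bin_edges, data_spectrum$bin_edges)))
      stop("all spectra must share identical bin edges", call. = FALSE)
    if (b$normalized) b else normalize_basis(b)
  })
  Phi <- vapply(bases, `[[`, numeric(length(data_spectrum$counts)),
                "counts")
  y <- data_spectrum$counts
  if (weighted) {
    wv <- 1 / pmax(y, 1)
    Phi_f <- Phi * sqrt(wv); y_f <- y * sqrt(wv)
  } else {
    Phi_f <- Phi; y_f <- y
  }
  cn <- kappa(Phi_f, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf(
      "basis spectra are (near-)collinear: condition number %.3g", cn),
      call. = FALSE)
  a <- if (nonneg) nnls_solve(Phi_f, y_f) else
    as.numeric(qr.solve(Phi_f, y_f))
  names(a) <- names(bases)
  res <- y_f - as.numeric(Phi_f %*% a)
  n <- length(y_f); p <- ncol(Phi_f)
  bin_var <- pmax(as.numeric(Phi %*% a), 1)  # Poisson variance estimate
  if (weighted) {
    V <- solve(crossprod(Phi / sqrt(bin_var)))
  } else {
    XtXi <- solve(crossprod(Phi))
    V <- XtXi %*% crossprod(Phi * bin_var, Phi) %*% XtXi
  }
  dimnames(V) <- list(names(a), names(a))
  structure(list(coefficients = a, vcov = V,
                 se = sqrt(pmax(diag(V), 0)),
                 fitted = as.numeric(Phi %*% a),
                 residuals = y - as.numeric(Phi %*% a),
                 data = data_spectrum, bases = bases,
                 nonneg = nonneg, weighted = weighted,
                 condition_number = cn, rss = sum(res^2),
                 df.residual = n - p),
            class = "qpid_deconv")
}

# Lawson-Hanson non-negative least squares (active set).  Small p only.
nnls_solve <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  pass <- logical(p)
  w <- as.numeric(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!pass) && max(w[!pass]) > tol * max(abs(w), 1)) {
    iter <- iter + 1L
    if (iter > 30L * p) break
    j <- which(!pass)[which.max(w[!pass])]
    pass[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[pass] <- as.numeric(qr.solve(A[, pass, drop = FALSE], b))
      if (all(z[pass] > 0)) { x <- z; break }
      q <- pass & z <= 0
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      pass <- pass & x > tol
      x[!pass] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' @export
coef.qpid_deconv <- function(object, ...) object$coefficients

#' @export
vcov.qpid_deconv <- function(object, ...) object$vcov

#' @export
fitted.qpid_deconv <- function(object, ...) object$fitted

#' @export
residuals.qpid_deconv <- function(object, ...) object$residuals

#' @export
print.qpid_deconv <- function(x, ...) {
  cat("Spectral deconvolution (", length(x$coefficients), " bases, ",
      if (x$nonneg) "A >= 0" else "unconstrained",
      if (x$weighted) ", Poisson-weighted" else "", ")\n", sep = "")
  print(data.frame(activity = x$coefficients, se = x$se))
  invisible(x)
}

#' @export
summary.qpid_deconv <- function(object, ...) {
  cat(sprintf(
    "Spectral deconvolution: %d bins, %d bases, RSS %.6g, cond %.3g\n",
    length(object$data$counts), length(object$coefficients),
    object$rss, object$condition_number))
  print(data.frame(activity = object$coefficients, se = object$se))
  invisible(object)
}

#' Percent injected activity
#'
#' `%IA = 100 * measured / injected`; both activities must be
#' decay-corrected to the same reference time.
#'
#' @param measured_bq measured activity, Bq.
#' @param injected_bq injected activity, Bq (> 0).
#' @return Percent injected activity.
#' @export
percent_injected_activity <- function(measured_bq, injected_bq) {
  stopifnot(all(injected_bq > 0))
  100 * measured_bq / injected_bq
}

#' Bioequivalence ratio of a theranostic pair
#'
#' `B = (therapeutic compound %IA) / (imaging surrogate %IA)`, e.g.
#' Ra-223 chloride over Na-F-18 in the same sample.
#'
#' @param ra_pct_ia %IA of the therapeutic compound.
#' @param f_pct_ia %IA of the imaging surrogate (> 0).
#' @return The dimensionless ratio B.
#' @export
bioequivalence <- function(ra_pct_ia, f_pct_ia) {
  if (any(f_pct_ia <= 0))
    stop("denominator %IA must be > 0", call. = FALSE)
  ra_pct_ia / f_pct_ia
}

#' Imager-to-dose-calibrator activity ratio
#'
#' `R = imager %IA / calibrator %IA`; since both share the same injected
#' activity the ratio is identical when computed from raw activities
#' (the IA cancels).
#'
#' @param qpid_pct_ia %IA (or activity) measured by the imager.
#' @param microdose_pct_ia %IA (or activity) measured by the dose
#'   calibrator (> 0).
#' @return The ratio R.
#' @export
qpid_microdose_ratio <- function(qpid_pct_ia, microdose_pct_ia) {
  if (any(microdose_pct_ia <= 0))
    stop("denominator must be > 0", call. = FALSE)
  qpid_pct_ia / microdose_pct_ia
}

#' Linearity / efficiency fit
#'
#' Ordinary least squares of observed event rate against known source
#' activity.  The slope is the detection efficiency (counts per decay);
#' the per-point percent residual `100 (obs - fit) / fit` flags
#' departures from linearity, with `abs(residual) > 10%` marking the
#' onset of saturation.
#'
#' @param activity_bq known activities, Bq (>= 2 distinct levels).
#' @param rate observed event rates, events/s.
#' @return An object of class `linearity_fit` with `coef`, `print`,
#'   `summary` methods; fields `slope`, `intercept`, `slope_se`,
#'   `residual_pct`, `nonlinear` (any residual over 10%).
#' @export
fit_linearity <- function(activity_bq, rate) {
  if (length(unique(activity_bq)) < 2L)
    stop("need at least 2 distinct activity levels", call. = FALSE)
  stopifnot(length(activity_bq) == length(rate))
  fit <- stats::lm(rate ~ activity_bq)
  pred <- stats::fitted(fit)
  res_pct <- 100 * (rate - pred) / pred
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 slope_se = cf[2L, 2L], intercept_se = cf[1L, 2L],
                 residual_pct = res_pct,
                 nonlinear = any(abs(res_pct) > 10),
                 activity_bq = activity_bq, rate = rate, lm = fit),
            class = "linearity_fit")
}

#' @export
coef.linearity_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "Linearity fit: efficiency (slope) %.4g +/- %.2g, intercept %.4g\n",
    x$slope, x$slope_se, x$intercept))
  cat(sprintf("  %% residuals in [%.2f, %.2f]%s\n",
              min(x$residual_pct), max(x$residual_pct),
              if (x$nonlinear) "  ** exceeds the 10% linearity bound **"
              else ""))
  invisible(x)
}

#' Decay correction to a reference time
#'
#' `activity * 2^(elapsed / half_life)`: the activity the sample had at
#' the reference time `elapsed` seconds before the measurement.
#'
#' @param activity measured activity.
#' @param elapsed_s time since the reference time, seconds.
#' @param half_life_s half-life, seconds (> 0).
#' @return Decay-corrected activity.
#' @export
decay_correct <- function(activity, elapsed_s, half_life_s) {
  stopifnot(all(half_life_s > 0))
  activity * 2^(elapsed_s / half_life_s)
}

#' Histogram peak widths (FWHM / FWTM)
#'
#' Full widths at half and tenth maximum by linear interpolation between
#' bin midpoints at the *outermost* crossings, so asymmetric and
#' flat-topped peaks (like the coincidence timing distribution) are
#' measured across their full extent.
#'
#' @param spectrum an `energy_spectrum` histogram with a single dominant
#'   peak.
#' @return Named numeric vector `c(fwhm, fwtm)` in the bin-edge units.
#' @export
hist_width <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  h <- level_crossings(spectrum, 0.5)
  t <- level_crossings(spectrum, 0.1)
  c(fwhm = h[2L] - h[1L], fwtm = t[2L] - t[1L])
}
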