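#' Binned energy spectra
#'
#' Container for binned spectra/histograms used both as deconvolution
#' bases and as timing histograms.  `bin_edges` (keV or ns) must be
#' strictly increasing; `counts` holds one non-negative value per bin.
#'
#' @param bin_edges numeric vector of monotone increasing bin edges.
#' @param counts non-negative numeric vector, `length(bin_edges) - 1`.
#' @param normalized logical; `TRUE` when the counts sum to one.
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(bin_edges, counts, normalized = FALSE) {
  bin_edges <- as.numeric(bin_edges); counts <- as.numeric(counts)
  if (length(counts) != length(bin_edges) - 1L)
    stop("need length(counts) == length(bin_edges) - 1", call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (isTRUE(normalized) && abs(sum(counts) - 1) > 1e-9)
    stop("spectrum flagged normalized but counts sum to ",
         format(sum(counts)), call. = FALSE)
  structure(list(bin_edges = bin_edges, counts = counts,
                 normalized = isTRUE(normalized)),
            class = "energy_spectrum")
}

#' Bin samples into an energy spectrum
#'
#' @param x numeric samples (keV, ns, ...).
#' @param breaks bin edges, or a single bin width used to span the data.
#' @return An `energy_spectrum`.
#' @export
bin_spectrum <- function(x, breaks) {
  x <- x[is.finite(x)]
  if (length(breaks) == 1L) {
    w <- breaks
    lo <- floor(min(x) / w) * w
    hi <- ceiling(max(x) / w) * w
    if (hi <= lo) hi <- lo + w
    breaks <- seq(lo, hi, by = w)
  }
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = FALSE),
                  nbins = length(breaks) - 1L)
  energy_spectrum(breaks, cnt)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("energy_spectrum: %d bins over [%g, %g], total %g%s\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

bin_mids <- function(s) (s$bin_edges[-1L] + s$bin_edges[-length(s$bin_edges)]) / 2

#' Normalize a basis spectrum to unit sum
#'
#' Basis spectra used for spectral deconvolution are normalized so their
#' counts sum to one; the fitted amplitudes then carry the activity scale.
#' Already-normalized spectra pass through unchanged.
#'
#' @param spectrum an `energy_spectrum`.
#' @return The normalized `energy_spectrum`.
#' @export
normalize_basis <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  tot <- sum(spectrum$counts)
  if (tot <= 0) stop("cannot normalize an empty spectrum", call. = FALSE)
  energy_spectrum(spectrum$bin_edges, spectrum$counts / tot,
                  normalized = TRUE)
}

#' Peak position of a spectrum
#'
#' Midpoint of the outermost half-maximum crossings, the same convention
#' [hist_width()] uses; stable for flat-topped peaks (e.g. alpha lines
#' broadened by the spread in mylar energy loss).
#'
#' @param spectrum an `energy_spectrum` with a single dominant peak.
#' @return Peak position in the units of `bin_edges`.
#' @export
spectrum_peak <- function(spectrum) {
  cr <- level_crossings(spectrum, frac = 0.5)
  (cr[1L] + cr[2L]) / 2
}

# Outermost crossings of counts at frac * max, by linear interpolation
# between bin midpoints.  Returns c(left, right).
level_crossings <- function(spectrum, frac) {
  y <- spectrum$counts
  if (all(y == 0)) stop("all-zero histogram", call. = FALSE)
  x <- bin_mids(spectrum)
  lev <- frac * max(y)
  above <- which(y >= lev)
  i <- above[1L]; j <- above[length(above)]
  left <- if (i == 1L) spectrum$bin_edges[1L] else {
    x[i - 1L] + (lev - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
  }
  right <- if (j == length(y)) spectrum$bin_edges[length(spectrum$bin_edges)] else {
    x[j] + (y[j] - lev) / (y[j] - y[j + 1L]) * (x[j + 1L] - x[j])
  }
  c(left, right)
}
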