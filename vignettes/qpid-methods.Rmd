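---
title: "Methods: coincidence particle-identification autoradiography processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coincidence particle-identification autoradiography processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpid)
```

## The measurement model

The package processes list-mode data from a quantitative
particle-identification autoradiograph: a 256 × 256 pixelated silicon
sensor (55 µm pitch, 1.4 × 1.4 cm² field of view, 1.5625 ns time
quantum) reads out every ionized pixel as an individual record
(column, row, time of arrival, time over threshold), while a
scintillator channel records gamma pulses (time, pulse area) on a
common clock.  A charged particle crossing the sensor ionizes a
cluster of pixels — a *track* — whose geometry identifies the particle
class: alphas produce compact, roughly circular blobs more than
400 µm across; betas produce thin chains with scattering kinks.

Processing proceeds in stages, each usable on its own:

1. **Track building.** Two hits join when they are within the
   aggregation window in time *and* within the adjacency radius in
   Chebyshev pixel distance; tracks are the connected components of
   that graph (union-find, so the partition is independent of input
   order).  Linking is chain-transitive: a track may span more than
   one window end-to-end.  Track energy is the sum of pixel energies,
   track time the unweighted mean of hit times, track position the
   energy-weighted centroid.
2. **Coincidence matching.** A track is tagged with the nearest gamma
   within the coincidence window (|Δt| ≤ window); matching is
   one-to-one, nearest-|Δt| first, earlier track on ties.  The
   accidental (randoms) rate for independent streams is
   `r_tracks × r_gammas × τ`, and the coincidence signal-to-noise
   ratio is the true coincidence rate over that.
3. **Particle identification.** `alpha` requires a circular topology
   *and* at least 3 MeV; `beta` requires at most 1 MeV; everything
   else is `unknown`.  β⁻ and β⁺ tracks are morphologically
   identical, so β⁺ selection uses only the coincident annihilation
   gamma (≥ 450 keV).  Circularity is decided on two moments:
   *elongation* = √(λ₂/λ₁) of the energy-weighted second-moment
   matrix, and *fill fraction* = pixel count over the lattice size of
   the filled convex hull.
4. **Imaging.** Event-map images deposit every track pixel (1/N per
   pixel in activity scaling, the pixel energy in spectroscopic
   scaling); centroid images deposit the whole track at its centroid
   (1, or the track energy).  Unnormalized activity grids therefore
   sum to the track count and spectroscopic grids to the total
   deposited energy — the conservation checks the tests rely on.
   Time normalization gives events/s/pixel; spectroscopic images are
   additionally divided by the pixel area (3.025 × 10⁻³ mm²) to give
   MeV/s/mm².
5. **Quantification.** Spectral deconvolution solves
   S_i = Σ_j A_j φ_ij in least squares with unit-normalized bases
   φ and A_j ≥ 0; linearity fits regress observed rate on known
   activity and flag |residual| > 10 %; decay correction multiplies
   by 2^(elapsed/half-life); the bioequivalence ratio B divides the
   %IA of the therapeutic compound by the %IA of the imaging
   surrogate, and the imager/calibrator ratio R is identical whether
   computed from %IA or raw activities because the injected activity
   cancels.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| aggregation window | 40 ns | covers the 22 ns FWTM of the intra-track timing spread with margin |
| adjacency radius | 2 px (Chebyshev) | bridges diagonal steps and single dead pixels |
| coincidence window | 60 ns | covers the 34.4 ns FWTM of the coincidence timing spread |
| beta ceiling | 1000 keV | betas deposit under ~1 MeV |
| alpha floor | 3000 keV | alphas arrive at several MeV even after mylar losses |
| gamma floor (β⁺ filter) | 450 keV | selects the 511 keV annihilation photopeak |
| circularity | elongation ≥ 0.6 and fill ≥ 0.6 | minimal two-moment realization of a circle-versus-line filter |
| Auger window | 5–20 keV (inclusive) | isolates 12.7 keV Auger tracks for sharp imaging |

Window-semantics note: coincidence acceptance is two-sided
(|Δt| ≤ 60 ns), while `randoms_rate()` multiplies by the *stated*
window length, reproducing the instrument's published arithmetic
(100/s × 100/s × 60 ns = 0.0006 events/s) exactly; the matching
acceptance of a uniform background is 2 × window, which the
truth-based tests account for.

## What the synthetic source emulates

The simulator exists so every stage is testable without hardware.  It
draws Poisson decay counts (activity × duration), walks the shipped
decay chains (²²³Ra: 4 α + 2 β⁻ to stable ²⁰⁷Pb; ²²⁷Th: one more α;
¹⁸F: a single β⁺; ⁸⁹Zr: a 12.7 keV Auger branch and a β⁺ branch with
mean 395.5 keV, endpoint 902 keV), and renders:

* **Alpha discs** — filled pixel discs with diameter drawn at
  450 ± 40 µm and a truncated-Gaussian radial energy profile.  The
  measured energy is compressed above a 3 MeV knee (slope 0.72),
  emulating high-LET saturation, after a uniform 1.5–2 MeV mylar
  loss.  The secondary alpha calibration
  (`fit_alpha_transform`) must undo exactly this family, which is why
  a piecewise-linear map through measured/reference peak pairs
  suffices and why held-out chain lines validate to better than 2 %.
* **Beta chains** — persistent self-avoiding lattice walks (heading
  kept with probability 0.95, otherwise scattered), giving the
  linear-with-kinks morphology; path length follows the surrogate
  L = round(0.11 · E^0.87) pixels, tuned once so a 12.7 keV Auger
  spans ~1 pixel and a 900 keV endpoint beta spans ~40.  The exponent
  is a free morphology parameter, not a physics claim.
* **Timing** — per-hit jitter is an exponentially modified Gaussian
  (tail/core ratio 1) scaled so the intra-track residual histogram
  has a 7.7 ns FWHM, reproducing the right-skewed shape of the real
  distribution; gamma coincidence jitter is Gaussian at 24.2 ns FWHM.
  All times are quantized to 1.5625 ns.
* **Gamma channel** — each β⁺ yields, with probability 0.023, a
  511 keV gamma (20 keV Gaussian resolution) at the emission time
  plus jitter, over Poisson background singles.

Emission times default to *equilibrium* timing: every chain emission
gets an independent uniform time over the acquisition, which is how a
secularly equilibrated source behaves when daughter half-lives
(seconds to minutes) dwarf the 40 ns clustering window.  The `prompt`
option instead stamps daughters with the parent decay time; it keeps
per-decay bookkeeping exact but makes chain siblings share a position
*and* a timestamp, so the clusterer necessarily merges them — useful
only when track-level counting is not the object of study.

The simulator does **not** model charge transport or diffusion,
energy straggling, delta rays, detector dead time or readout
bandwidth rolloff, charge sharing between pixels, the ~15 ns flat top
of the real coincidence timing distribution, or tissue attenuation.
Passing tests therefore demonstrate the correctness of the
*processing chain* under the stated statistical model, not detector
physics fidelity.

## Numerical choices

* Clustering uses union-find with path compression over time-sorted
  hits and a sliding window, equivalent (and tested equal) to the
  brute-force transitive closure of the pairwise predicate.
* Width estimation (`hist_width`) interpolates linearly between bin
  midpoints at the *outermost* half/tenth-maximum crossings, so
  flat-topped and asymmetric peaks are measured across their full
  extent.  `spectrum_peak` reports the midpoint of the half-maximum
  crossings, which is stable for the box-like alpha peaks produced
  by the uniform mylar loss.
* Line profiles are sampled at pixel resolution with perpendicular
  averaging; sub-pixel crossing positions come from a cubic-spline
  refinement of the sampled profile (linear interpolation alone
  overestimates the width of a σ ≈ 1.4 px ridge by ~7 %; the spline
  brings recovery to well under 5 %).
* Centroid binning takes the floor of the fractional coordinates; no
  sub-pixel spreading.
* Deconvolution solves the unweighted normal equations (QR) and, for
  the A ≥ 0 constraint, a small Lawson–Hanson active set.  Reported
  uncertainties use the sandwich covariance with fitted values as
  Poisson bin variances: against 1σ intervals this gives ~68 %
  empirical coverage, where naive residual-variance scaling measures
  ~47 % on the same problem.  A Poisson-weighted fit is available but
  off by default so the unweighted formulation remains the reference.
* Images are stored as single-channel 32-bit TIFF rasters scaled by
  the image maximum (recorded in a JSON sidecar); quantisation is
  below 2⁻³² of the maximum and the reader inverts the writer's
  quantisation convention, so integer-level grids round-trip exactly.
  Log₁₀(1 + x) scaling is applied only to the optional display
  rendering, never to the quantitative file.
* Degenerate inputs: zero-activity scenes simulate to empty but valid
  outputs; an all-zero histogram has no width; a flat profile has no
  FWHM; a zero-energy track has no centroid; collinear deconvolution
  bases raise an error carrying the condition number.

## Test problem sizes

The suite clusters random fields up to 500 hits against the
brute-force oracle (100 instances), classifies 10⁴ + 10⁴ rendered
alpha/beta tracks for the >99 % precision/recall check, uses 10⁶
Monte Carlo directions for the hemisphere acceptance (±0.002), 10⁵
decays for the detections-per-decay expectation, 100 Poisson
replicates at activities (400, 100) for deconvolution bias and
coverage, and 300–4000-decay acquisitions for the timing closed loops
(7.7 ns intra-track, 24.2 ns coincidence, both recovered within
10 %).

## Known limitations

Pile-up of genuinely overlapping particles is not resolved; the beta
range surrogate is not a transport model; alpha saturation is a
two-parameter piecewise-linear stand-in; the equilibrium timing mode
ignores daughter ingrowth dynamics; ROI uncertainty is reported as
the standard error of the pixel mean, which understates uncertainty
for spatially correlated images.
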