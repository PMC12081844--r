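#' Built-in nuclide decay chains
#'
#' Decay chains used by the synthetic source: each row is one decay step
#' with parent, mode (`alpha`, `beta_minus`, `beta_plus`, `auger`),
#' an emission-energy model, a branching fraction and the daughter.
#' Alpha and Auger steps carry a fixed line energy; beta steps carry a
#' mean and endpoint and are sampled from a beta-distribution surrogate
#' spectrum with that mean.  Rows sharing a parent are branches whose
#' fractions sum to one.
#'
#' Shipped chains: `"Ra-223"` (4 alpha + 2 beta-minus steps to stable
#' Pb-207), `"Th-227"` (Ra-223 chain plus the parent alpha, modelled with
#' its two main lines at 6038/5756 keV), `"F-18"` (a single beta-plus;
#' the ~3% electron-capture branch is folded in so one positron is
#' emitted per decay), and `"Zr-89"` (12.7 keV Auger branch and a
#' beta-plus branch with mean 395.5 keV, endpoint 902 keV).
#'
#' @param name chain name, e.g. `"Ra-223"`.
#' @return A data frame of class `nuclide_chain` with columns `parent`,
#'   `mode`, `energy_kev`, `beta_mean_kev`, `beta_endpoint_kev`,
#'   `branching`, `daughter`.
#' @examples
#' chain_emission_counts(nuclide_chain("Ra-223"))  # 4 alpha, 2 beta-minus
#' @export
nuclide_chain <- function(name) {
  steps <- switch(name,
    "Ra-223" = ra223_steps(),
    "Th-227" = rbind(
      chain_step("Th-227", "alpha", 6038, branching = 0.5, daughter = "Ra-223"),
      chain_step("Th-227", "alpha", 5756, branching = 0.5, daughter = "Ra-223"),
      ra223_steps()),
    "F-18" = chain_step("F-18", "beta_plus", NA,
                        beta_mean = 249.8, beta_endpoint = 633.5,
                        daughter = "O-18"),
    "Zr-89" = rbind(
      chain_step("Zr-89", "auger", 12.7, branching = 0.773,
                 daughter = "Y-89"),
      chain_step("Zr-89", "beta_plus", NA, beta_mean = 395.5,
                 beta_endpoint = 902, branching = 0.227,
                 daughter = "Y-89")),
    stop("unknown chain '", name, "'", call. = FALSE))
  as_nuclide_chain(steps, head = name)
}

chain_step <- function(parent, mode, energy_kev, beta_mean = NA,
                       beta_endpoint = NA, branching = 1, daughter) {
  data.frame(parent = parent, mode = mode,
             energy_kev = as.numeric(energy_kev),
             beta_mean_kev = as.numeric(beta_mean),
             beta_endpoint_kev = as.numeric(beta_endpoint),
             branching = branching, daughter = daughter,
             stringsAsFactors = FALSE)
}

ra223_steps <- function() rbind(
  chain_step("Ra-223", "alpha", 5716, daughter = "Rn-219"),
  chain_step("Rn-219", "alpha", 6819, daughter = "Po-215"),
  chain_step("Po-215", "alpha", 7386, daughter = "Pb-211"),
  chain_step("Pb-211", "beta_minus", NA, beta_mean = 471,
             beta_endpoint = 1373, daughter = "Bi-211"),
  chain_step("Bi-211", "alpha", 6622, daughter = "Tl-207"),
  chain_step("Tl-207", "beta_minus", NA, beta_mean = 492,
             beta_endpoint = 1423, daughter = "Pb-207"))

#' Build a chain from a step table
#' @param steps data frame of decay steps (see [nuclide_chain()]).
#' @param head name of the chain head nuclide; defaults to the first parent.
#' @return A validated `nuclide_chain`.
#' @export
as_nuclide_chain <- function(steps, head = steps$parent[1L]) {
  stopifnot(all(c("parent", "mode", "branching", "daughter") %in%
                  names(steps)))
  ok_modes <- c("alpha", "beta_minus", "beta_plus", "auger")
  if (!all(steps$mode %in% ok_modes))
    stop("unknown decay mode(s): ",
         paste(setdiff(steps$mode, ok_modes), collapse = ", "),
         call. = FALSE)
  br <- tapply(steps$branching, steps$parent, sum)
  if (any(abs(br - 1) > 1e-9))
    stop("branching fractions out of ",
         paste(names(br)[abs(br - 1) > 1e-9], collapse = ", "),
         " do not sum to 1", call. = FALSE)
  attr(steps, "head") <- head
  class(steps) <- c("nuclide_chain", "data.frame")
  expected_visits(steps)  # errors on cycles / non-termination
  steps
}

# Expected number of decays of each nuclide per decay of the chain head,
# by topological propagation of branching fractions.  Errors on cycles.
expected_visits <- function(chain) {
  head <- attr(chain, "head")
  visits <- c(structure(1, names = head))
  frontier <- head
  hops <- 0L
  while (length(frontier)) {
    hops <- hops + 1L
    if (hops > nrow(chain) + 1L)
      stop("decay chain does not terminate (cycle detected)", call. = FALSE)
    nxt <- character()
    for (p in frontier) {
      rows <- chain[chain$parent == p, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        d <- rows$daughter[k]
        inc <- visits[[p]] * rows$branching[k]
        visits[d] <- if (d %in% names(visits)) visits[[d]] + inc else inc
        if (d %in% chain$parent) nxt <- union(nxt, d)
      }
    }
    frontier <- nxt
  }
  visits
}

#' Charged-emission multiplicity of a decay chain
#'
#' Walks the chain from its head to the stable endpoint and returns the
#' branch-weighted expected number of alpha, beta-minus and beta-plus
#' emissions per decay of the head nuclide.  For Ra-223 this is
#' (4, 2, 0); for F-18 it is (0, 0, 1).
#'
#' @param chain a `nuclide_chain`.
#' @return Named numeric vector `c(n_alpha, n_beta_minus, n_beta_plus)`.
#' @export
chain_emission_counts <- function(chain) {
  stopifnot(inherits(chain, "nuclide_chain"))
  visits <- expected_visits(chain)
  w <- visits[chain$parent] * chain$branching
  tot <- function(mode) sum(w[chain$mode == mode])
  c(n_alpha = tot("alpha"), n_beta_minus = tot("beta_minus"),
    n_beta_plus = tot("beta_plus"))
}

#' Nuclide half-lives
#'
#' Editable lookup of half-lives for the shipped nuclides (standard
#' nuclear-data values).
#' @return `qpid_half_lives()`: data frame with `nuclide`, `half_life_s`.
#'   `half_life_s(nuclide)`: seconds.
#' @param nuclide nuclide name, e.g. `"F-18"`.
#' @export
qpid_half_lives <- function() {
  data.frame(
    nuclide = c("F-18", "Ra-223", "Zr-89", "Th-227"),
    half_life_s = c(109.77 * 60, 11.43 * 86400, 78.4 * 3600, 18.7 * 86400),
    stringsAsFactors = FALSE)
}

#' @rdname qpid_half_lives
#' @export
half_life_s <- function(nuclide) {
  tbl <- qpid_half_lives()
  i <- match(nuclide, tbl$nuclide)
  if (any(is.na(i)))
    stop("no half-life on record for ",
         paste(nuclide[is.na(i)], collapse = ", "), call. = FALSE)
  tbl$half_life_s[i]
}

# Sample one emission energy (keV) for a chain step row.  Beta spectra use
# a Beta(2, b) surrogate on [0, endpoint] with b set so the mean matches
# the tabulated mean energy.
sample_step_energy <- function(step, n = 1L) {
  if (step$mode %in% c("alpha", "auger")) return(rep(step$energy_kev, n))
  m <- step$beta_mean_kev / step$beta_endpoint_kev
  a <- 2
  b <- a * (1 - m) / m
  step$beta_endpoint_kev * stats::rbeta(n, a, b)
}
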