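shared_bases <- function() {
  edges <- seq(0, 8000, by = 100)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  a <- normalize_basis(energy_spectrum(
    edges, stats::dnorm(mid, 5700, 250) + stats::dnorm(mid, 6800, 250)))
  b <- normalize_basis(energy_spectrum(
    edges, stats::dbeta(pmin(mid / 1400, 1), 2, 3.1)))
  list(edges = edges, alpha = a, beta = b)
}

test_that("basis normalization is idempotent and sums to one", {
  s <- energy_spectrum(c(0, 1, 2), c(2, 2))
  n <- normalize_basis(s)
  expect_equal(n$counts, c(0.5, 0.5))
  expect_lt(abs(sum(n$counts) - 1), 1e-9)
  expect_equal(normalize_basis(n)$counts, n$counts)
  expect_error(normalize_basis(energy_spectrum(c(0, 1), 0)), "empty")
})

test_that("noiseless mixtures are identified exactly", {
  b <- shared_bases()
  s <- energy_spectrum(b$edges, 2 * b$alpha$counts + 3 * b$beta$counts)
  fit <- deconvolve_activities(s, list(ra = b$alpha, f = b$beta))
  expect_lt(max(abs(coef(fit) - c(2, 3))), 1e-8)
  # single basis
  s1 <- energy_spectrum(b$edges, 5 * b$alpha$counts)
  expect_lt(abs(coef(deconvolve_activities(s1, list(a = b$alpha))) - 5),
            1e-8)
})

test_that("constrained fit equals the least-squares oracle when the
           oracle is non-negative", {
  b <- shared_bases()
  set.seed(90)
  Phi <- cbind(b$alpha$counts, b$beta$counts)
  y <- rpois(length(b$alpha$counts), as.numeric(Phi %*% c(400, 100)))
  oracle <- as.numeric(qr.solve(Phi, y))
  stopifnot(all(oracle >= 0))
  s <- energy_spectrum(b$edges, y)
  con <- coef(deconvolve_activities(s, list(a = b$alpha, f = b$beta)))
  unc <- coef(deconvolve_activities(s, list(a = b$alpha, f = b$beta),
                                    nonneg = FALSE))
  expect_lt(max(abs(con - oracle) / oracle), 1e-6)
  expect_lt(max(abs(unc - oracle)), 1e-10)
})

test_that("the non-negativity constraint binds where the oracle is
           negative", {
  b <- shared_bases()
  set.seed(91)
  # data from the alpha basis only: the beta amplitude wants to go
  # slightly negative on noise in some replicates
  found_active <- FALSE
  for (r in 1:20) {
    y <- rpois(length(b$alpha$counts), 120 * b$alpha$counts)
    s <- energy_spectrum(b$edges, y)
    unc <- coef(deconvolve_activities(s, list(a = b$alpha, f = b$beta),
                                      nonneg = FALSE))
    con <- coef(deconvolve_activities(s, list(a = b$alpha, f = b$beta)))
    expect_true(all(con >= 0))
    if (any(unc < 0)) {
      found_active <- TRUE
      expect_equal(unname(con[unc < 0]), rep(0, sum(unc < 0)))
    }
  }
  expect_true(found_active)
})

test_that("Poisson replicates recover activities without bias and with
           calibrated uncertainties", {
  b <- shared_bases()
  set.seed(92)
  truth <- c(400, 100)
  nrep <- 100
  est <- matrix(0, nrep, 2); hit <- 0L
  for (r in seq_len(nrep)) {
    y <- rpois(length(b$alpha$counts),
               truth[1] * b$alpha$counts + truth[2] * b$beta$counts)
    fit <- deconvolve_activities(energy_spectrum(b$edges, y),
                                 list(a = b$alpha, f = b$beta))
    est[r, ] <- coef(fit)
    hit <- hit + sum(abs(coef(fit) - truth) <= fit$se)
  }
  expect_lt(max(abs(colMeans(est) - truth) / truth), 0.02)
  cover <- hit / (2 * nrep)
  expect_gte(cover, 0.60)
  expect_lte(cover, 0.75)
})

test_that("collinear bases are rejected with a condition number", {
  b <- shared_bases()
  near <- energy_spectrum(b$edges, b$alpha$counts * (1 + 1e-12))
  near$normalized <- TRUE
  s <- energy_spectrum(b$edges, b$alpha$counts)
  expect_error(deconvolve_activities(s, list(a = b$alpha, b = near)),
               "condition number")
})

test_that("%IA, bioequivalence and imager/calibrator ratios", {
  expect_equal(percent_injected_activity(5, 5), 100)
  expect_equal(percent_injected_activity(0, 5), 0)
  # residual correction shrinks the denominator, %IA rises monotonically
  inj <- seq(10, 5, by = -1)
  expect_true(all(diff(percent_injected_activity(3, inj)) > 0))

  expect_equal(bioequivalence(0.5, 1), 0.5)
  expect_equal(bioequivalence(2, 2), 1)
  expect_error(bioequivalence(1, 0), "> 0")

  # Eq-identity: ratio from %IA equals ratio from raw activities
  set.seed(17)
  act_q <- runif(20, 1, 100); act_m <- runif(20, 1, 100)
  inj <- runif(20, 100, 1000)
  r_pct <- qpid_microdose_ratio(percent_injected_activity(act_q, inj),
                                percent_injected_activity(act_m, inj))
  r_act <- qpid_microdose_ratio(act_q, act_m)
  expect_lt(max(abs(r_pct - r_act)), 1e-12)
})

test_that("a planted linear attenuation series is recovered by
           regression on the thickness ratios", {
  set.seed(18)
  thick <- c(10, 20, 30, 50)
  slope_true <- -0.0049; icpt_true <- 0.701
  ratio <- icpt_true + slope_true * thick + rnorm(4, 0, 1e-4)
  fit <- stats::lm(ratio ~ thick)
  expect_lt(abs(unname(coef(fit)[2]) - slope_true), 5e-4)
  expect_lt(abs(unname(coef(fit)[1]) - icpt_true), 5e-3)
})

test_that("linearity fits report efficiency and percent residuals", {
  act <- c(50, 100, 200, 400, 700)
  fit <- suppressWarnings(fit_linearity(act, 2.49 * act))  # exact line
  expect_equal(fit$slope, 2.49)
  expect_equal(max(abs(fit$residual_pct)), 0, tolerance = 1e-10)
  expect_false(fit$nonlinear)
  expect_equal(unname(coef(fit)["slope"]), 2.49)

  # saturating response trips the 10% flag above the knee
  rate <- 0.476 * act; rate[act > 300] <- 0.476 * 300
  fit2 <- fit_linearity(act, rate)
  expect_true(fit2$nonlinear)
  expect_lt(min(fit2$residual_pct[act > 300]), -10)

  # OLS residuals sum to ~0 around the fitted line
  set.seed(3)
  r3 <- 2 * act + rnorm(5, 0, 5)
  fit3 <- fit_linearity(act, r3)
  expect_lt(abs(sum(r3 - stats::fitted(fit3$lm))), 1e-9)
  expect_error(fit_linearity(c(100, 100), c(1, 2)), "distinct")
})

test_that("decay correction composes and doubles per half-life", {
  expect_equal(decay_correct(10, 3600, 3600), 20)
  expect_equal(decay_correct(10, 0, 3600), 10)
  two_step <- decay_correct(decay_correct(7, 1000, 6586.2), 2000, 6586.2)
  expect_equal(two_step, decay_correct(7, 3000, 6586.2))
})

test_that("hist_width matches the Gaussian closed forms and handles
           degenerate shapes", {
  set.seed(19)
  x <- rnorm(4e5, 0, 10)
  w <- hist_width(bin_spectrum(x, 0.5))
  expect_lt(abs(w["fwhm"] - 2 * sqrt(2 * log(2)) * 10) /
              (2 * sqrt(2 * log(2)) * 10), 0.02)
  expect_lt(abs(w["fwtm"] - 2 * sqrt(2 * log(10)) * 10) /
              (2 * sqrt(2 * log(10)) * 10), 0.02)

  # single occupied bin
  s1 <- energy_spectrum(c(0, 1, 2, 3), c(0, 7, 0))
  expect_lte(hist_width(s1)["fwhm"], 1)

  # flat-topped pulse: outermost crossings span at least the plateau
  splat <- energy_spectrum(0:12, c(0, 0, 1, 10, 10, 10, 10, 10, 1, 0, 0, 0))
  expect_gte(hist_width(splat)["fwhm"], 5)
  expect_error(hist_width(energy_spectrum(0:3, c(0, 0, 0))), "all-zero")
})
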