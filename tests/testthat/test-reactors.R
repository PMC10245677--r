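test_that("internal-age distributions have the printed forms", {
  pfr <- internal_age(reactor_spec("pfr", 5))
  expect_equal(pfr$icdf(0.6), 3)
  cstr <- internal_age(reactor_spec("cstr", 5))
  expect_equal(cstr$icdf(0.5), 5 * log(2))
  lfr <- internal_age(reactor_spec("lfr", 4))
  expect_equal(lfr$icdf(0.75), 4)
  expect_equal(lfr$icdf(0.25), 1)
  expect_error(pfr$icdf(1), "0, 1")
})

test_that("each age pdf integrates to one and inverts its cdf", {
  for (kind in c("pfr", "cstr", "lfr")) {
    spec <- reactor_spec(kind, 3.2)
    age <- internal_age(spec)
    # split at the LFR kink; the power-law tail needs the infinite-domain rule
    mass <- integrate(age$pdf, 0, spec$T / 2, rel.tol = 1e-10)$value +
      integrate(age$pdf, spec$T / 2, age$upper, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
    p <- seq(0.01, 0.985, by = 0.02)
    expect_equal(age$cdf(age$icdf(p)), p, tolerance = 1e-10)
  }
})

test_that("inverse-transform sampling reproduces the internal-age law", {
  grid_t <- seq(0.01, 8, by = 0.01)
  for (kind in c("pfr", "cstr", "lfr")) {
    spec <- reactor_spec(kind, 2)
    age <- internal_age(spec)
    ages <- sample_ages(spec, 1e5, seed = 3, method = "icdf")
    expect_lt(max(abs(ecdf(ages)(grid_t) - age$cdf(grid_t))), 0.01)
    # the explicit observation-window construction agrees at its own sample
    # size (~ n * T / window cells are present at the observation time)
    aw <- sample_ages(spec, 1e5, seed = 4, method = "window")
    expect_gt(length(aw), 1500)
    expect_lt(max(abs(ecdf(aw)(grid_t) - age$cdf(grid_t))),
              2.5 / sqrt(length(aw)))
  }
})

test_that("quantile maps between reactor clocks are rank-preserving", {
  pfr <- reactor_spec("pfr", 5); cstr <- reactor_spec("cstr", 5)
  expect_equal(transform_times(c(1, 2.5, 4), pfr, pfr), c(1, 2.5, 4))
  expect_equal(transform_times(2.5, pfr, cstr), -5 * log(0.5), tolerance = 1e-12)
  x <- sort(runif(20, 0, 4.9))
  expect_false(is.unsorted(transform_times(x, pfr, cstr)))
  expect_false(is.unsorted(transform_times(x, pfr, reactor_spec("lfr", 5))))
})

test_that("the transient GF starts at the bivariate Poisson initial law", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  p0 <- transient_pmf(pars, t = 0, shape = c(25, 25))
  expect_lt(max(abs(unclass(p0) -
                    outer(dpois(0:24, pars$lambdaN0), dpois(0:24, pars$lambdaM0)))),
            1e-12)
})

test_that("a constant burst profile relaxes to the stationary bursty law", {
  pars <- transient_params(b = c(3, 3, 3), tau = c(1, 2),
                           alpha = 1, beta = 0.9, gamma = 1.1)
  pT <- transient_pmf(pars, t = 60, shape = c(30, 30))
  pS <- gf_to_pmf(bursty_model(1, 3, 0.9, 1.1), shape = c(30, 30))
  expect_lt(tv(pT, pS), 1e-4)
})

test_that("the transient PMF matches the exact simulation law mid-transition", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  pm <- transient_pmf(pars, t = 2, shape = c(25, 25))
  x <- ssa_transient(pars, ages = 2, seed = 1, reps = 1e5)
  expect_lt(tv(unclass(pm), empirical_pmf2(x, c(25, 25))), 0.03)
})

test_that("transient PMFs are valid distributions at every time", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  for (t in c(0.5, 1.5, 3.5, 7)) {
    p <- transient_pmf(pars, t, shape = c(25, 25))
    expect_true(all(p >= 0))
    expect_lt(attr(p, "normalization_defect"), 1e-6)
  }
})

test_that("quadrature recycling equals per-cell dense quadrature", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  set.seed(7)
  times <- sort(runif(10, 0, 5))
  x <- ssa_transient(pars, ages = times, seed = 3)
  shape <- apply(x, 2, max) + 5L
  ll_naive <- transient_loglik(x, times, pars, shape = shape, naive = TRUE,
                               naive_nodes = 2000)
  ll_fast <- transient_loglik(x, times, pars, shape = shape)
  expect_lt(abs(ll_fast - ll_naive), 1e-3)
})

test_that("a single time reduces the batch evaluator to the direct GF", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  pb <- batch_transient_pmfs(pars, times = 2, shape = c(25, 25))[[1]]
  pd <- transient_pmf(pars, t = 2, shape = c(25, 25))
  expect_lt(max(abs(unclass(pb) - unclass(pd))), 1e-4)
  expect_error(batch_transient_pmfs(pars, times = c(3, 1), shape = c(25, 25)),
               "sorted")
})

test_that("the shared-grid matrix is lower triangular and Toeplitz when uniform", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  qm <- quadrature_matrices(pars, times = seq(0.5, 4, by = 0.5))
  expect_true(all(qm$TQ[upper.tri(qm$TQ)] == 0))
  # uniform grid: constant diagonals (Toeplitz) on the lower triangle
  for (k in 0:(nrow(qm$TQ) - 2)) {
    d <- qm$TQ[row(qm$TQ) - col(qm$TQ) == k]
    expect_equal(max(d) - min(d), 0)
  }
})

test_that("reactor marginalization has the right limits and averages", {
  K <- 2; gam <- 0.5; Tr <- 4
  gf_t <- function(U, t) burstgf:::gf_eval(constitutive_model(K, gam), U, t = t)
  # constant-in-time GF is unchanged
  gconst <- function(U, t) exp(1.7 * U[, 1])
  U <- matrix(-0.4 + 0.3i, 1, 1)
  expect_equal(reactor_marginal_gf(gconst, reactor_spec("cstr", 2), U),
               exp(1.7 * U[1, 1]), tolerance = 1e-9)
  # PFR over a constitutive model started empty: analytic time-averaged mean
  g <- spectral_grid(24)
  pm <- burstgf:::pmf_from_gf_values(
    reactor_marginal_gf(gf_t, reactor_spec("pfr", Tr), g$u), 24)
  mean_analytic <- integrate(function(t) (K / gam) * (1 - exp(-gam * t)) / Tr,
                             0, Tr)$value
  expect_equal(sum((0:23) * as.numeric(pm)), mean_analytic, tolerance = 1e-6)
  # CSTR with T -> 0 recovers the initial distribution (all mass at zero)
  p0 <- burstgf:::pmf_from_gf_values(
    reactor_marginal_gf(gf_t, reactor_spec("cstr", 1e-6), g$u), 24)
  expect_gt(p0[1], 1 - 1e-4)
})
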