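test_that("encapsulation transforms follow the droplet-number PGFs", {
  # poisson lambda = 0: all droplets empty
  e0 <- encapsulation_gf(encapsulation_spec("poisson", lambda = 0), 0.3 + 0.1i)
  expect_equal(e0, 1 + 0i)
  # bernoulli p = 1 is the identity
  e1 <- encapsulation_gf(encapsulation_spec("bernoulli", p = 1), 0.3 + 0.1i)
  expect_equal(e1, 0.3 + 0.1i)
  # bernoulli p = 0.3 on a Poisson(2) cell: 0.7 delta0 + 0.3 Poisson(2)
  m <- constitutive_model(2, 1)
  p <- gf_to_pmf(m, shape = 24,
                 noise = noise_stack(encapsulation = encapsulation_spec("bernoulli", p = 0.3)))
  expect_lt(max(abs(as.numeric(p) - (0.7 * c(1, rep(0, 23)) + 0.3 * dpois(0:23, 2)))),
            1e-12)
  expect_error(encapsulation_spec("bernoulli", p = 2), "0, 1")
})

test_that("background is independent Poisson with pseudobulk means", {
  bg <- background_gf(background_spec(1e-4, mu = c(10, 20)))
  U <- matrix(c(-0.2 + 0.1i, -0.5 - 0.3i), 1, 2)
  expect_equal(bg(U), exp(1e-4 * (10 * U[1, 1] + 20 * U[1, 2])))
  # c = 0: GF identically one
  expect_equal(background_gf(background_spec(0, mu = c(1, 2)))(U), 1 + 0i)
  # sampled moments: independent Poisson means c*mu, zero cross-covariance
  g <- spectral_grid(c(14, 14))
  vals <- background_gf(background_spec(0.05, mu = c(10, 20)))(g$u)
  p <- burstgf:::pmf_from_gf_values(vals, c(14, 14))
  mom <- pmf_moments(p)
  expect_equal(mom$mean, c(0.5, 1.0), tolerance = 1e-7)
  expect_lt(abs(mom$cov[1, 2]), 1e-7)
})

test_that("empty droplets carry background alone under Bernoulli encapsulation", {
  m <- constitutive_model(4, 1)
  stack <- noise_stack(encapsulation = encapsulation_spec("bernoulli", p = 0.4),
                       background = background_spec(0.1))
  p <- gf_to_pmf(m, shape = 32, noise = stack)
  # total law = 0.6 * Poisson(c*mu) + 0.4 * Poisson(4 + c*mu)
  mix <- 0.6 * dpois(0:31, 0.4) + 0.4 * dpois(0:31, 4.4)
  expect_lt(max(abs(as.numeric(p) - mix)), 1e-10)
})

test_that("library-construction substitutions act per species", {
  U <- matrix(c(-0.2 + 0.1i, -0.5 - 0.3i), 1, 2)
  # sequestering p = 1 is the identity
  expect_equal(library_gf(library_noise("sequestering", p = c(1, 1)), U), U)
  # sequestering on Poisson is thinning
  m <- constitutive_model(5, 1)
  p <- gf_to_pmf(m, shape = 24,
                 noise = noise_stack(library = library_noise("sequestering", p = 0.3)))
  expect_lt(max(abs(as.numeric(p) - dpois(0:23, 1.5))), 1e-12)
  # non-sequestering lambda = 0.1 on Poisson(5): per-molecule Poisson counts
  pn <- gf_to_pmf(m, shape = 16,
                  noise = noise_stack(library = library_noise("non_sequestering",
                                                              lambda = 0.1)))
  set.seed(11)
  xs <- rpois(1e5, 0.1 * rpois(1e5, 5))
  expect_lt(tv(as.numeric(pn), empirical_pmf(xs, 16)), 0.01)
})

test_that("sequestering noise equals explicit binomial thinning of the PMF", {
  m <- bursty_model(1, 4.9, 0.7, species = "one")
  base <- gf_to_pmf(m, shape = 256)
  for (p in c(0.25, 0.6)) {
    obs <- gf_to_pmf(m, shape = 128,
                     noise = noise_stack(library = library_noise("sequestering", p = p)))
    expect_lt(tv(as.numeric(obs), thin_pmf(as.numeric(base), p, 127)), 1e-8)
  }
})

test_that("ambiguity transforms are row-stochastic coordinate maps", {
  expect_error(ambiguity_matrix(matrix(c(0.5, 0.2, 0.4, 0.3), 2, 2)),
               "summing to 1")
  # identity matrix changes nothing
  P <- ambiguity_matrix(diag(2))
  U <- matrix(c(-0.2 + 0.1i, -0.5 - 0.3i), 1, 2)
  expect_equal(ambiguity_transform(P, U), U)
  # total-count collapse: both source coordinates equal the single observed one
  Pc <- ambiguity_matrix(matrix(c(1, 1), 2, 1))
  Uc <- matrix(-0.3 + 0.2i, 1, 1)
  expect_equal(as.vector(ambiguity_transform(Pc, Uc)), rep(Uc[1, 1], 2))
  # collapse of independent Poissons(2, 4) is Poisson(6)
  m <- monomolecular_model(2, 1, 0.5)
  pt <- gf_to_pmf(m, shape = 40, noise = noise_stack(ambiguity = Pc))
  expect_lt(max(abs(as.numeric(pt) - dpois(0:39, 6))), 1e-10)
})

test_that("three-class ambiguity preserves the total-count law", {
  m <- monomolecular_model(2, 1, 0.5)
  P <- ambiguity_matrix(matrix(c(0.8, 0, 0.2,
                                 0, 0.7, 0.3), 2, 3, byrow = TRUE))
  p3 <- gf_to_pmf(m, shape = c(24, 24, 24), noise = noise_stack(ambiguity = P))
  totals <- numeric(40)
  idx <- expand.grid(0:23, 0:23, 0:23)
  tot <- rowSums(idx)
  pv <- as.vector(unclass(p3))
  for (k in 0:39) totals[k + 1] <- sum(pv[tot == k])
  expect_lt(tv(totals, dpois(0:39, 6)), 1e-8)
})

test_that("full composition is normalized and reduces to the model GF", {
  m <- bursty_model(1, 3, 0.7, 0.9)
  id_stack <- noise_stack()
  gfc <- burstgf:::composed_gf(m, id_stack)
  U <- matrix(c(-0.2 + 0.1i, -0.5 - 0.3i), 1, 2)
  expect_equal(gfc(U), burstgf:::gf_eval(m, U))
  full <- burstgf:::composed_gf(m, noise_stack(
    encapsulation = encapsulation_spec("bernoulli", p = 0.8),
    background = background_spec(0.01),
    library = library_noise("sequestering", p = c(0.6, 0.5)),
    ambiguity = ambiguity_matrix(diag(2))))
  expect_lt(abs(full(matrix(0 + 0i, 1, 2)) - 1), 1e-10)
})

test_that("bursty observed PMFs depend only on (b pN, pM / pN)", {
  mk <- function(b, pN, pM)
    gf_to_pmf(bursty_model(1, b, 0.7, 0.9), shape = c(40, 40),
              noise = noise_stack(library = library_noise("sequestering",
                                                          p = c(pN, pM))))
  pA <- mk(4.9 / 0.5, 0.5, 0.25)
  pB <- mk(4.9 / 0.8, 0.8, 0.40)
  expect_lt(max(abs(unclass(pA) - unclass(pB))), 1e-10)
})

test_that("slow-driver laws are invariant to (pN, pM) rescalings fixing theta*p/rate", {
  # mixture limit: bivariate NB GF (1 - th pN uN / beta - th pM uM / gamma)^(-v)
  nb2 <- function(theta, beta, gamma, pN, pM) {
    function(U) (1 - theta * (pN * U[, 1] / beta + pM * U[, 2] / gamma))^(-3)
  }
  g <- spectral_grid(c(30, 30))
  pA <- burstgf:::pmf_from_gf_values(nb2(1, 0.8, 0.9, 0.5, 0.25)(g$u), c(30, 30))
  # rescale: pN' = 1, theta' pN'/beta' must match -> beta' = beta/ (0.5), etc.
  pB <- burstgf:::pmf_from_gf_values(nb2(1, 0.8 / 0.5, 0.9 / 0.25, 1, 1)(g$u), c(30, 30))
  expect_lt(max(abs(unclass(pA) - unclass(pB))), 1e-12)
})
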