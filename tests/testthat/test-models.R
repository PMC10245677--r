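test_that("closed-form stationary laws carry the right parameters", {
  cf <- stationary_closed_form("constitutive", list(K = 2, gamma = 1))
  expect_equal(cf$lambda, 2)
  expect_equal(cf$dpmf(0:5), dpois(0:5, 2))

  # autocatalytic alpha = 1, q = 0.5, gamma = 1: NB shape 2, scale 1
  cf2 <- stationary_closed_form(autocatalytic_model(1, 0.5, 1))
  expect_equal(cf2$shape, 2)
  expect_equal(cf2$scale, 1)

  # bursty alpha = 1, beta = 0.7, b = 4.9: shape ~ 1.43, scale 4.9
  cf3 <- stationary_closed_form("bursty", list(alpha = 1, b = 4.9, beta = 0.7))
  expect_equal(cf3$shape, 1 / 0.7)
  expect_equal(round(cf3$shape, 2), 1.43)
  expect_equal(cf3$scale, 4.9)

  expect_error(stationary_closed_form("cir", list()), class = "no_closed_form")
})

test_that("autocatalytic stationary law matches its GF and the CME oracle", {
  m <- autocatalytic_model(1, 0.5, 1)
  p <- gf_to_pmf(m, shape = 64)
  expect_lt(max(abs(as.numeric(p) - dnbinom(0:63, size = 2, prob = 0.5))), 1e-8)
})

test_that("bursty-autocatalytic GF has the closed form and its limits", {
  # u = 0 normalization
  g <- bursty_autocat_gf(1, 0.3, 1, 2)
  expect_equal(g(0 + 0i), 1 + 0i)
  # q -> 0 reduces to the stationary bursty NB GF (1 - b u)^(-alpha/gamma)
  gq <- bursty_autocat_gf(2, 1e-9, 1.3, 3)
  u <- -0.4 + 0.25i
  expect_equal(gq(u), (1 - 3 * u)^(-2 / 1.3), tolerance = 1e-6)
  # stationarity guard
  expect_error(bursty_autocat_gf(1, 0.9, 1, 2), "stationarity")
})

test_that("bursty-autocatalytic PMF matches the exact simulation law", {
  g <- bursty_autocat_gf(1, 0.3, 1, 2)
  grid <- spectral_grid(64)
  p <- burstgf:::pmf_from_gf_values(g(grid$u[, 1]), 64)
  x <- ssa_autocatalytic(1, 0.3, 1, 2, t_end = 30, reps = 1e5, seed = 5)
  expect_lt(tv(as.numeric(p), empirical_pmf(x, 64)), 0.02)
})

test_that("two-gene state coupling factorizes at epsilon = 1", {
  pars <- list(epsilon = 1, kon = 0.7, koff = 0.8, kinit = 3,
               gamma1 = 1, gamma2 = 1.3)
  joint <- gf_to_pmf(build_coupled_model("state_coupled", pars), shape = c(14, 14))
  m1 <- gf_to_pmf(telegraph_model(0.7, 0.8, 3, 1, species = "one"), shape = 14)
  m2 <- gf_to_pmf(telegraph_model(0.7, 0.8, 3, 1.3, species = "one"), shape = 14)
  expect_lt(tv(unclass(joint), outer(as.numeric(m1), as.numeric(m2))), 1e-5)
})

test_that("unstable intermediate states converge to the reduced co-bursting chain", {
  pars <- list(epsilon = 1e-3, kon = 0.7, koff = 0.8, kinit = 3,
               gamma1 = 1, gamma2 = 1.3)
  full <- gf_to_pmf(build_coupled_model("state_coupled", pars), shape = c(14, 14))
  red <- gf_to_pmf(build_coupled_model("cobursting_n2", pars), shape = c(14, 14))
  expect_lt(tv(full, red), 0.01)
  # reduced rates from the fast-intermediate limit
  m2 <- build_coupled_model("cobursting_n2", pars)
  expect_equal(m2$params$kon_star, 2 * 0.7^2 / 1.5)
  expect_equal(m2$params$koff_star, 2 * 0.8^2 / 1.5)
})

test_that("cell-type mixtures decompose into conditional products", {
  comp <- list(list(constitutive_model(2, 1), constitutive_model(3, 1)))
  gf1 <- build_coupled_model("mixture", list(pi = 1, components = comp))
  U <- matrix(c(-0.3 + 0.2i, -0.7 - 0.4i), 1, 2)
  expect_equal(gf1(U), exp(2 * U[, 1]) * exp(3 * U[, 2]), tolerance = 1e-9)
  expect_error(build_coupled_model("mixture", list(pi = c(0.5, 0.4),
                                                   components = list(comp[[1]], comp[[1]]))),
               "sum to 1")
  # two components with distinct rates: GF is the weighted sum
  comp2 <- list(comp[[1]], list(constitutive_model(6, 1), constitutive_model(1, 1)))
  gf2 <- build_coupled_model("mixture", list(pi = c(0.25, 0.75), components = comp2))
  expect_equal(gf2(U),
               0.25 * exp(2 * U[, 1] + 3 * U[, 2]) + 0.75 * exp(6 * U[, 1] + U[, 2]),
               tolerance = 1e-9)
})

test_that("a shared continuous driver correlates the genes it feeds", {
  p <- list(kappa = 0.3, a = 0.6, theta = 2, gamma1 = 1, gamma2 = 1.3)
  m <- build_coupled_model("driver_shared", p)
  pj <- gf_to_pmf(m, shape = c(34, 30))
  mom <- pmf_moments(pj)
  muK <- p$a * p$theta / p$kappa
  expect_equal(mom$mean, c(muK / 1, muK / 1.3), tolerance = 1e-3)
  expect_gt(mom$cov[1, 2] / sqrt(mom$cov[1, 1] * mom$cov[2, 2]), 0.1)
  # each marginal equals the corresponding one-gene driver model
  m1 <- gou_model(p$kappa, p$a, p$theta, beta = 1, species = "one")
  expect_lt(tv(pmf_marginal(pj, 1), as.numeric(gf_to_pmf(m1, shape = 34))), 1e-6)
})

test_that("invalid rates are rejected by the family builders", {
  expect_error(telegraph_model(-1, 1, 5, 1, 1), "positive")
  expect_error(autocatalytic_model(1, 2, 1), "gamma > q")
  expect_error(bursty_model(1, -2, 1, 1), "positive")
})
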