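test_that("simulations are bit-for-bit reproducible under a fixed seed", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  a <- ssa_transient(pars, ages = c(1, 2, 4), seed = 17, reps = 3)
  b <- ssa_transient(pars, ages = c(1, 2, 4), seed = 17, reps = 3)
  expect_identical(a, b)
  expect_identical(ssa_autocatalytic(1, 0.3, 1, 2, 5, 100, seed = 4),
                   ssa_autocatalytic(1, 0.3, 1, 2, 5, 100, seed = 4))
  d1 <- simulate_droplets(genes = 4, n_cells = 50, n_empty = 50, seed = 23)
  d2 <- simulate_droplets(genes = 4, n_cells = 50, n_empty = 50, seed = 23)
  expect_identical(d1$nascent, d2$nascent)
  expect_identical(d1$mature, d2$mature)
})

test_that("silencing transcription collapses the counts to zero", {
  # with a vanishing burst frequency both the Poisson initial load
  # (alpha*b1/rate) and the burst influx vanish
  pars <- transient_params(b = c(2, 2, 2), tau = c(1, 3),
                           alpha = 1e-9, beta = 1.2, gamma = 0.7)
  x <- ssa_transient(pars, ages = c(0.5, 1.5), seed = 2, reps = 500)
  expect_true(all(x == 0L))
})

test_that("the simulated transient means track the GF-derived means", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 0.9)
  for (t in c(0.8, 2.2)) {
    x <- ssa_transient(pars, ages = t, seed = 40 + round(10 * t), reps = 20000)
    mom <- pmf_moments(transient_pmf(pars, t, shape = c(28, 28)))
    expect_equal(mean(x[, 1]), mom$mean[1], tolerance = 0.03)
    expect_equal(mean(x[, 2]), mom$mean[2], tolerance = 0.03)
  }
})

test_that("constant-burst simulations reach the stationary bursty law", {
  pars <- transient_params(b = c(3, 3, 3), tau = c(1, 2),
                           alpha = 1, beta = 0.9, gamma = 1.1)
  x <- ssa_transient(pars, ages = 50, seed = 9, reps = 1e5)
  pS <- gf_to_pmf(bursty_model(1, 3, 0.9, 1.1), shape = c(30, 30))
  expect_lt(tv(empirical_pmf2(x, c(30, 30)), unclass(pS)), 0.02)
})

test_that("stage changes move the nascent mean toward the new stage value", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  x1 <- ssa_transient(pars, ages = 0.99, seed = 31, reps = 30000)
  x2 <- ssa_transient(pars, ages = 3.0, seed = 32, reps = 30000)
  m1 <- mean(x1[, 1]); m2 <- mean(x2[, 1])
  expect_equal(m1, 0.8 * 2 / 1.2, tolerance = 0.05)   # stage-1 stationary mean
  expect_gt(m2, m1)                                    # moving toward alpha*b2/beta
  expect_lt(abs(m2 - 0.8 * 5 / 1.2) / (0.8 * 5 / 1.2), 0.15)
})

test_that("rejection sampling honors the clip domain and moment rule", {
  accept_rule <- function(p) {
    bmax <- max(p$b)
    muN <- p$alpha * bmax / p$beta; muM <- p$alpha * bmax / p$gamma
    sdN <- sqrt(muN * (1 + bmax))
    sdM <- sqrt(muM * (1 + bmax * p$beta / (p$beta + p$gamma)))
    muN + 4 * sdN < 25 && muM + 4 * sdM < 25
  }
  for (r in 1:50) {
    p <- draw_transient_params(seed = derive_seed(99, r))
    v <- c(p$b, p$alpha, p$beta, p$gamma)
    expect_true(all(v >= 10^-1.4 - 1e-12 & v <= 10^1.4 + 1e-12))
    expect_true(accept_rule(p))
  }
})

test_that("molecule-level count noise matches its generating-function law", {
  # thinning halves a Poisson mean
  x <- matrix(rpois(2e4, 4), ncol = 1)
  y <- apply_count_noise(x, library_noise("sequestering", p = 0.5), seed = 3)
  expect_equal(mean(y), 2, tolerance = 0.05)
  # identity at p = 1
  expect_identical(apply_count_noise(x, library_noise("sequestering", p = 1),
                                     seed = 1)[, 1], x[, 1])
  # non-sequestering on NB counts vs the composed-GF PMF
  m <- bursty_model(1, 4.9, 0.7, species = "one")
  base <- gf_to_pmf(m, shape = 64)
  xs <- sample_pmf(base, 1e5, seed = 5)
  noised <- apply_count_noise(xs, library_noise("non_sequestering", lambda = 0.2),
                              seed = 6)
  pgf <- gf_to_pmf(m, shape = 24,
                   noise = noise_stack(library = library_noise("non_sequestering",
                                                               lambda = 0.2)))
  expect_lt(tv(empirical_pmf(pmin(noised[, 1], 23L), 24), as.numeric(pgf)), 0.02)
})

test_that("droplet datasets separate Poisson empties from overdispersed cells", {
  dd <- simulate_droplets(genes = 12, n_cells = 800, n_empty = 10000,
                          c_bg = 0.05, seed = 4)
  emp <- dd$labels == "empty"
  # per-gene Fano ~ 1 in empties, total-count Fano ~ 1
  mv <- mean_variance_table(dd$mature[emp, ])
  expect_lt(max(abs(mv$var / mv$mean - 1)), 0.2)
  expect_lt(abs(total_count_fano(dd$mature[emp, ]) - 1), 0.1)
  # c_bg = 0 silences the empties entirely
  d0 <- simulate_droplets(genes = 4, n_cells = 20, n_empty = 50, c_bg = 0, seed = 5)
  expect_true(all(d0$mature[d0$labels == "empty", ] == 0L))
})

test_that("the aggregate channel inflates only the flagged genes", {
  dd <- simulate_droplets(genes = 10, n_cells = 100, n_empty = 10000, c_bg = 0.05,
                          aggregate = list(genes = c(2, 7), rate = 0.05, size = 8),
                          seed = 8)
  emp <- dd$labels == "empty"
  mv <- mean_variance_table(dd$mature[emp, ])
  fano <- mv$var / mv$mean
  expect_true(all(fano[c(2, 7)] > 2))
  expect_true(all(fano[-c(2, 7)] < 1.5))
})
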