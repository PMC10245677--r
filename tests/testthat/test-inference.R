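test_that("count log-likelihood is additive and bounded by the grid", {
  p <- gf_to_pmf(constitutive_model(2, 1), shape = 16)
  # a single cell at the mode contributes log of that mass
  expect_equal(count_loglik(matrix(2L, 1, 1), p), log(p[3]))
  # duplicated data exactly double the log-likelihood
  x <- matrix(c(0L, 1L, 4L), ncol = 1)
  expect_equal(count_loglik(rbind(x, x), p), 2 * count_loglik(x, p))
  expect_error(count_loglik(matrix(50L, 1, 1), p), "outside")
})

test_that("mean per-cell log-likelihood approaches the negative entropy", {
  p <- gf_to_pmf(constitutive_model(2, 1), shape = 24)
  set.seed(3)
  x <- matrix(rpois(5e4, 2), ncol = 1)
  H <- -sum(dpois(0:23, 2) * log(dpois(0:23, 2)), na.rm = TRUE)
  expect_equal(count_loglik(x, p) / nrow(x), -H, tolerance = 0.02)
})

test_that("Akaike weights follow the stabilized definition", {
  # equal logL and parameter count: uniform weights
  w <- akaike_weights(c(-50, -50, -50), npar = 2)
  expect_equal(w$weight, rep(1 / 3, 3))
  expect_equal(w$delta[1], 0)
  # direct evaluation of the definition: AIC deltas (0, 2, 6) give weights
  # proportional to (1, e^-1, e^-3)
  w2 <- akaike_weights(c(-100, -101, -103), npar = 4)
  ref <- c(1, exp(-1), exp(-3)) / sum(c(1, exp(-1), exp(-3)))
  expect_equal(w2$weight, ref, tolerance = 1e-12)
  expect_equal(round(ref, 4), c(0.7054, 0.2595, 0.0351))
  expect_equal(sum(w2$weight), 1)
  # dominance limit
  w3 <- akaike_weights(c(-10, -60), npar = 1)
  expect_gt(w3$weight[1], 1 - 1e-10)
  # invariance to adding a constant to all logL values
  w4 <- akaike_weights(c(-100, -101, -103) + 57.3, npar = 4)
  expect_equal(w4$weight, w2$weight, tolerance = 1e-12)
  expect_error(akaike_weights(-3), "at least two")
})

test_that("the bounded MLE improves on its initialization and honors bounds", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  pfr <- reactor_spec("pfr", 5)
  ages <- sort(sample_ages(pfr, 60, seed = 11))
  x <- ssa_transient(pars, ages, seed = 12)
  fit <- fit_transient(x, ages, pfr, tau = c(1, 3), init = pars)
  expect_gte(fit$logLik, transient_loglik(x, ages, pars) - 1e-6)
  expect_true(all(fit$par >= -1.5 & fit$par <= 1.5))
  expect_s3_class(fit, "transient_fit")
  expect_equal(unname(coef(fit, log10 = TRUE)), fit$par)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  pr <- predict(fit, times = c(1, 2))
  expect_length(pr, 2)
  expect_lt(attr(pr[[1]], "normalization_defect"), 1e-6)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(nrow(sim), 2 * length(ages))
})

test_that("the MLE recovers most log-parameters from a PFR snapshot", {
  pars <- transient_params(b = c(2, 5, 1), tau = c(1, 3),
                           alpha = 0.8, beta = 1.2, gamma = 3.14)
  pfr <- reactor_spec("pfr", 5)
  hits <- vapply(1:3, function(r) {
    ages <- sort(sample_ages(pfr, 200, seed = derive_seed(60, r)))
    x <- ssa_transient(pars, ages, seed = derive_seed(61, r))
    fit <- fit_transient(x, ages, pfr, tau = c(1, 3), init = pars)
    truth <- log10(c(pars$b, pars$alpha, pars$beta, pars$gamma))
    sum(abs(fit$par - truth) <= 0.3)
  }, 1)
  # at least 4 of 6 log-parameters within 0.3 of truth, majority of replicates
  expect_gte(median(hits), 4)
})

test_that("nascent likelihood landscapes localize the truth only up to a ridge", {
  hits_nasc <- logical(5)
  impostor_below <- logical(3)
  for (r in 1:5) {
    truth <- gou_model(0.1, 0.4, 1, 0.8, 0.9)
    pt <- gf_to_pmf(truth, shape = c(50, 51))
    xs <- sample_pmf(pt, 200, seed = derive_seed(70, r))
    ls <- likelihood_landscape(xs, "gou", muK = 4, beta = 0.8, gamma = 0.9,
                               mode = "nascent")
    i <- which.min(abs(ls$x - 1 / 9)); j <- which.min(abs(ls$y - 5 / 7))
    hits_nasc[r] <- ls$top_decile[i, j]
    if (r <= 3) {
      lsb <- likelihood_landscape(xs, "gou", muK = 4, beta = 0.8, gamma = 0.9,
                                  mode = "bivariate")
      # the burst-like impostor (two-species x ~ 0.81, y = 5/7) falls out of
      # the top decile once the joint structure is used
      ib <- which.min(abs(lsb$x - 0.809)); jb <- which.min(abs(lsb$y - 5 / 7))
      impostor_below[r] <- !lsb$top_decile[ib, jb]
    }
  }
  expect_gte(sum(hits_nasc), 3)
  expect_gte(sum(impostor_below), 2)
})

test_that("a size-zero dataset yields a flat landscape", {
  ls <- likelihood_landscape(matrix(integer(), 0, 2), "gou", muK = 4,
                             beta = 0.8, gamma = 0.9, nx = 3, ny = 3)
  expect_true(all(ls$logL == 0))
})

test_that("model weights collapse to 1/3 in the Poisson limit and separate regimes", {
  # y -> 0: all three drivers converge to the same Poisson law, so the mean
  # truth weight approaches the uninformative 1/3 from above
  dev <- vapply(c(0.6, 0.2, 0.01), function(y) {
    w <- model_weight_landscape(rbind(c(0.5, y)), truth = "gou",
                                n_cells = 200, reps = 3, seed = 5)
    abs(w$weight - 1 / 3)
  }, 1)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.1)
  # the mixture-like node is far better identified than the burst-like node
  wl <- model_weight_landscape(rbind(c(0.4, 0.9), c(0.9, 0.8)), truth = "gou",
                               n_cells = 200, reps = 5, seed = 6)
  expect_gt(wl$weight[1], wl$weight[2])
  # equal seeds with one rep are deterministic
  w1 <- model_weight_landscape(rbind(c(0.4, 0.9)), reps = 1, seed = 9)
  w2 <- model_weight_landscape(rbind(c(0.4, 0.9)), reps = 1, seed = 9)
  expect_identical(w1$weight, w2$weight)
})

test_that("the capture-ratio posterior is consistent and sharpens with cells", {
  shape <- c(60, 70)
  lr <- 10^seq(-2, 2, length.out = 120)
  tab <- ratio_pmf_table(lr, shape = shape)
  truth1 <- ratio_pmf_table(1, shape = shape)[[1]]
  post_means <- vapply(1:6, function(k) {
    xs <- sample_pmf(truth1, 200, seed = derive_seed(80, k))
    rp <- ratio_posterior(xs, table = tab, ngrid = 120)
    expect_equal(sum(rp$posterior), 1, tolerance = 1e-12)
    rp$mean_log10_ratio
  }, 1)
  expect_lt(abs(mean(post_means)), 0.3)

  truth4 <- ratio_pmf_table(4, shape = shape)[[1]]
  psd <- function(n, seed) {
    xs <- sample_pmf(truth4, n, seed = seed)
    rp <- ratio_posterior(xs, table = tab, ngrid = 120)
    sqrt(sum((rp$log10_ratio - rp$mean_log10_ratio)^2 * rp$posterior))
  }
  expect_gt(psd(20, 7), psd(200, 8))
})
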