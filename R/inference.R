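## Likelihood evaluation, bounded MLE for the transient model, Akaike-weight
## model selection, (x, y) likelihood landscapes, and the capture-ratio
## posterior.

#' Log-likelihood of counts under a PMF grid
#'
#' `sum_c log P(x_c)` with probabilities floored at `floor` (finite grids
#' truncate tails).
#'
#' @param x integer count matrix (observations x species) or vector.
#' @param pmf a `pmf_grid` whose axes cover the observed counts.
#' @param floor probability floor applied before the log.
#' @return scalar log-likelihood.
#' @export
count_loglik <- function(x, pmf, floor = 1e-12) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  d <- dim(pmf) %||% length(pmf)
  if (ncol(x) != length(d)) stop("count dimensionality does not match the PMF")
  if (any(x < 0) || any(sweep(x, 2, d, `>=`)))
    stop("observed counts fall outside the PMF grid; enlarge the grid")
  p <- unclass(pmf)[x + 1L]
  sum(log(pmax(p, floor)))
}

## Per-cell transient probabilities (recycled quadrature, compiled kernel).
## theta on the natural scale; ages must be sorted ascending.
transient_cell_probs <- function(theta, tau, ages, xN, xM, shape,
                                 dense_below = 100L, target_nodes = 1025L) {
  cpp_transient_cellprobs(theta, tau[1], tau[2], ages, as.integer(xN),
                          as.integer(xM), as.integer(shape[1]),
                          as.integer(shape[2]), as.integer(dense_below),
                          as.integer(target_nodes))
}

#' Transient-model log-likelihood
#'
#' Full log-likelihood of per-cell count pairs observed at known (possibly
#' clock-transformed) ages, using either the quadrature-recycling evaluator
#' or a naive dense per-cell trapezoidal quadrature (an independent
#' cross-check; much slower).
#'
#' @param counts matrix with columns `xN`, `xM`.
#' @param ages cell ages (same order as `counts`).
#' @param params a [transient_params()].
#' @param shape PMF evaluation grid; default `max(count) + 5` per species.
#' @param naive use the per-cell dense quadrature instead of recycling.
#' @param naive_nodes trapezoid nodes per cell in naive mode.
#' @param floor probability floor.
#' @return scalar log-likelihood.
#' @export
transient_loglik <- function(counts, ages, params, shape = NULL,
                             naive = FALSE, naive_nodes = 2000L,
                             floor = 1e-12) {
  counts <- as.matrix(counts)
  shape <- shape %||% (apply(counts, 2, max) + 5L)
  ord <- order(ages)
  ages_s <- ages[ord]; counts_s <- counts[ord, , drop = FALSE]
  th <- c(params$b, params$alpha, params$beta, params$gamma)
  if (!naive) {
    p <- transient_cell_probs(th, params$tau, ages_s, counts_s[, 1],
                              counts_s[, 2], shape)
    return(sum(log(pmax(p, floor))))
  }
  grid <- spectral_grid(shape)
  uN <- grid$u[, 1]; uM <- grid$u[, 2]
  be <- params$beta; ga <- params$gamma; al <- params$alpha
  bfun <- b_profile(params)
  ll <- 0
  ng <- prod(shape)
  for (c in seq_along(ages_s)) {
    tc <- ages_s[c]
    sv <- seq(0, tc, length.out = naive_nodes)
    f_prev <- NULL
    acc <- 0 + 0i
    for (j in seq_along(sv)) {
      z <- bfun(tc - sv[j]) * UN_char(uN, uM, sv[j], be, ga)
      f <- z / (1 - z)
      if (j > 1) acc <- acc + 0.5 * (sv[j] - sv[j - 1]) * (f_prev + f)
      f_prev <- f
    }
    lg <- params$lambdaN0 * UN_char(uN, uM, tc, be, ga) +
      params$lambdaM0 * uM * exp(-ga * tc) + al * acc
    G <- exp(lg)
    kN <- rep(0:(shape[1] - 1L), times = shape[2])
    kM <- rep(0:(shape[2] - 1L), each = shape[1])
    ph <- exp(-2i * pi * (kN * counts_s[c, 1] / shape[1] +
                          kM * counts_s[c, 2] / shape[2]))
    p <- Re(sum(G * ph)) / ng
    ll <- ll + log(max(p, floor))
  }
  ll
}

#' Fit the transient bursty model by bounded maximum likelihood
#'
#' Minimizes the negative log-likelihood over `log10` of the six parameters
#' `(b1, b2, b3, alpha, beta, gamma)` with box bounds `(-1.5, 1.5)` per
#' log-parameter (L-BFGS-B, at most 20 iterations, finite-difference
#' gradients), with cell ages and stage times quantile-mapped from the
#' clock of the architecture that generated them (`age_model`) to the
#' candidate reactor's clock.
#'
#' @param counts matrix with columns `xN`, `xM`.
#' @param ages cell ages under `age_model`'s clock.
#' @param reactor candidate [reactor_spec()] being fit.
#' @param age_model [reactor_spec()] under which `ages` and `tau` are
#'   expressed; defaults to `reactor` (no transformation).
#' @param tau untransformed stage-change times.
#' @param init initialization: a [transient_params()] or length-6 vector
#'   `(b1, b2, b3, alpha, beta, gamma)`.
#' @param shape PMF grid; default `max(count) + 5` per species.
#' @param maxit L-BFGS-B iteration cap.
#' @param bounds box bounds for each log10 parameter.
#' @return object of class `transient_fit`.
#' @export
fit_transient <- function(counts, ages, reactor, age_model = reactor,
                          tau = c(1, 3), init, shape = NULL,
                          maxit = 20L, bounds = c(-1.5, 1.5)) {
  counts <- as.matrix(counts)
  shape <- shape %||% (apply(counts, 2, max) + 5L)
  ages_k <- transform_times(ages, age_model, reactor)
  tau_k <- transform_times(tau, age_model, reactor)
  ord <- order(ages_k)
  ages_s <- ages_k[ord]
  xN <- as.integer(counts[ord, 1]); xM <- as.integer(counts[ord, 2])
  th0 <- if (inherits(init, "transient_params"))
    c(init$b, init$alpha, init$beta, init$gamma) else as.numeric(init)
  if (length(th0) != 6) stop("init must provide 6 parameters")
  l0 <- pmin(pmax(log10(th0), bounds[1]), bounds[2])
  nll <- function(lth) {
    th <- 10^lth
    p <- tryCatch(
      transient_cell_probs(th, tau_k, ages_s, xN, xM, shape),
      error = function(e) NULL)
    if (is.null(p)) return(1e10)
    -sum(log(pmax(p, 1e-12)))
  }
  f0 <- nll(l0)
  if (!is.finite(f0)) stop("non-finite objective at the initialization")
  opt <- optim(l0, nll, method = "L-BFGS-B", lower = bounds[1], upper = bounds[2],
               control = list(maxit = maxit, factr = 1e7))
  best <- if (opt$value <= f0) opt$par else l0
  val <- min(opt$value, f0)
  theta <- 10^best
  names(theta) <- c("b1", "b2", "b3", "alpha", "beta", "gamma")
  structure(list(
    par = best, theta = theta, logLik = -val, npar = 6L,
    counts = cbind(xN = xN, xM = xM), ages = ages_s,
    reactor = reactor, age_model = age_model, tau = tau, tau_k = tau_k,
    shape = shape, init = th0, optim = opt), class = "transient_fit")
}

fitted_params <- function(object) {
  transient_params(object$theta[1:3], object$tau_k, object$theta[4],
                   object$theta[5], object$theta[6])
}

#' @export
#' @method print transient_fit
print.transient_fit <- function(x, ...) {
  cat(sprintf("<transient_fit: %s reactor (T = %g), %d cells, logLik = %.3f>\n",
              toupper(x$reactor$kind), x$reactor$T, nrow(x$counts), x$logLik))
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.transient_fit <- function(object, log10 = FALSE, ...) {
  if (log10) setNames(object$par, names(object$theta)) else object$theta
}

#' @export
logLik.transient_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = nrow(object$counts),
            class = "logLik")
}

#' @export
summary.transient_fit <- function(object, ...) {
  cat(sprintf("Transient bursty model under the %s internal-age law\n",
              toupper(object$reactor$kind)))
  cat(sprintf("  cells: %d; grid: %s; stage times (transformed): %s\n",
              nrow(object$counts), paste(object$shape, collapse = " x "),
              paste(format(object$tau_k, digits = 4), collapse = ", ")))
  cat(sprintf("  logLik %.3f; AIC %.3f; optimizer %s after %d fn evals\n",
              object$logLik, -2 * object$logLik + 2 * object$npar,
              if (object$optim$convergence == 0) "converged" else "stopped",
              object$optim$counts[1]))
  cat("  estimates (log10 bounds [-1.5, 1.5]):\n")
  print(round(rbind(estimate = object$theta, log10 = object$par), 4))
  invisible(object)
}

#' @export
predict.transient_fit <- function(object, times = NULL, ...) {
  times <- sort(times %||% unique(object$ages))
  batch_transient_pmfs(fitted_params(object), times, object$shape)
}

#' @export
simulate.transient_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  ssa_transient(fitted_params(object), object$ages, seed = seed, reps = nsim)
}

#' @export
plot.transient_fit <- function(x, species = 1L, ...) {
  obs <- x$counts[, species]
  tab <- tabulate(obs + 1L, nbins = x$shape[species]) / length(obs)
  pmfs <- predict(x)
  avg <- Reduce(`+`, lapply(pmfs, function(p) pmf_marginal(p, species))) / length(pmfs)
  graphics::barplot(tab, names.arg = seq_along(tab) - 1,
                    main = sprintf("pooled %s marginal",
                                   c("nascent", "mature")[species]),
                    xlab = "count", ylab = "probability", border = NA)
  xs <- seq_along(avg) - 0.5 + 0.2 * seq_along(avg)
  graphics::lines(xs, avg, col = "red3", lwd = 2)
  invisible(x)
}

#' Akaike weights from fitted models
#'
#' `AIC_k = -2 logL_k + 2 s_k`, `Delta_k = AIC_k - min AIC`,
#' `w_k = exp(-Delta_k/2) / sum_j exp(-Delta_j/2)` (stabilized by the
#' subtraction; ties in the minimum are irrelevant to the weights).
#'
#' @param logLik vector of maximized log-likelihoods, or a list of
#'   `transient_fit`s.
#' @param npar parameter counts (recycled).
#' @param names optional model names.
#' @return data.frame of class `akaike_result` with columns `logLik`,
#'   `npar`, `AIC`, `delta`, `weight`.
#' @export
akaike_weights <- function(logLik, npar = NULL, names = NULL) {
  if (is.list(logLik)) {
    names <- names %||% vapply(logLik, function(f) f$reactor$kind, "")
    npar <- npar %||% vapply(logLik, function(f) f$npar, 1L)
    logLik <- vapply(logLik, function(f) f$logLik, 1)
  }
  if (length(logLik) < 2) stop("at least two models are required")
  npar <- rep(npar %||% 0L, length.out = length(logLik))
  aic <- -2 * logLik + 2 * npar
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = names %||% paste0("model", seq_along(logLik)),
                    logLik = logLik, npar = npar, AIC = aic, delta = delta,
                    weight = w)
  class(out) <- c("akaike_result", "data.frame")
  out
}

#' Fit all three reactor architectures and weight them
#'
#' @inheritParams fit_transient
#' @param T mean residence time shared by the candidates.
#' @param ... passed to [fit_transient()].
#' @return list with the fits and the [akaike_weights()] table.
#' @export
select_reactor <- function(counts, ages, age_model, T = age_model$T,
                           tau = c(1, 3), init, ...) {
  kinds <- c("pfr", "cstr", "lfr")
  fits <- lapply(kinds, function(k)
    fit_transient(counts, ages, reactor_spec(k, T), age_model = age_model,
                  tau = tau, init = init, ...))
  names(fits) <- kinds
  list(fits = fits, weights = akaike_weights(fits))
}

## ---- (x, y) landscapes ----------------------------------------------------

## Stationary PMF of a driver family at qualitative coordinates; nascent
## mode evaluates the one-axis marginal directly (uM pinned at 0).
xy_pmf <- function(family, x, y, muK, beta, gamma, shape,
                   mode = c("bivariate", "nascent"), ...) {
  mode <- match.arg(mode)
  model <- model_at_xy(x, y, muK, beta, gamma, family, species = "two")
  ## the evaluation domain is fixed by convention; extreme coordinates may
  ## truncate and are handled by the likelihood floor, so no warning here
  if (mode == "bivariate") return(gf_to_pmf(model, shape = shape, warn = FALSE, ...))
  grid <- spectral_grid(shape[1])
  U <- cbind(grid$u, matrix(0 + 0i, nrow(grid$u), 1 + model$m))
  vals <- gf_eval(model, U, t = "stationary", ...)
  pmf_from_gf_values(vals, shape[1], warn = FALSE)
}

#' Log-likelihood landscape over the qualitative parameter square
#'
#' Evaluates the data log-likelihood of one driver family on a uniformly
#' spaced grid of (timescale separation x, noise intensity y), holding the
#' averages (`muK`, `beta`, `gamma`) fixed, using the nascent marginal or
#' the full bivariate counts.  The top decile of log-likelihoods (the least
#' distinguishable region) is returned as a mask.
#'
#' @param counts count matrix (`xN`, `xM`).
#' @param family `"gou"`, `"cir"` or `"telegraph"`.
#' @param muK,beta,gamma fixed averages.
#' @param mode `"nascent"` or `"bivariate"`.
#' @param nx,ny grid sizes (default 14 x 15 on [0.01, 0.99]).
#' @param bounds grid bounds.
#' @param shape PMF evaluation grid (default `[0..49] x [0..50]`).
#' @return list of class `landscape_grid`: `x`, `y`, `logL` matrix
#'   (`nx x ny`), `top_decile` logical mask.
#' @export
likelihood_landscape <- function(counts, family, muK, beta, gamma,
                                 mode = c("nascent", "bivariate"),
                                 nx = 14L, ny = 15L, bounds = c(0.01, 0.99),
                                 shape = c(50L, 51L)) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  xs <- seq(bounds[1], bounds[2], length.out = nx)
  ys <- seq(bounds[1], bounds[2], length.out = ny)
  L <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (nrow(counts) == 0) { L[i, j] <- 0; next }
    pmf <- xy_pmf(family, xs[i], ys[j], muK, beta, gamma, shape, mode)
    L[i, j] <- if (mode == "nascent") count_loglik(counts[, 1, drop = FALSE], pmf)
               else count_loglik(counts[, 1:2], pmf)
  }
  mask <- L >= quantile(L, 0.9)
  structure(list(x = xs, y = ys, logL = L, top_decile = mask,
                 family = family, mode = mode), class = "landscape_grid")
}

#' Average true-model Akaike weight at qualitative coordinates
#'
#' At each requested (x, y) node: simulate `reps` datasets of `n_cells`
#' cells from the truth family, evaluate the likelihood of all three driver
#' families at the same node with perfectly known parameters (no fitting;
#' equal parameter counts), and average the truth's Akaike weight.
#'
#' @param nodes two-column matrix of (x, y) coordinates.
#' @param truth family generating the data.
#' @param muK,beta,gamma fixed averages.
#' @param n_cells,reps dataset size and replicate count.
#' @param mode `"nascent"` or `"bivariate"`.
#' @param shape PMF evaluation grid.
#' @param seed integer seed.
#' @return data.frame with the node coordinates and mean truth weight.
#' @export
model_weight_landscape <- function(nodes, truth = "gou", muK = 5, beta = 0.8,
                                   gamma = 0.9, n_cells = 200L, reps = 50L,
                                   mode = c("nascent", "bivariate"),
                                   shape = c(50L, 51L), seed = 1L) {
  mode <- match.arg(mode)
  nodes <- matrix(nodes, ncol = 2)
  fams <- c("gou", "cir", "telegraph")
  out <- data.frame(x = nodes[, 1], y = nodes[, 2], weight = NA_real_)
  for (r in seq_len(nrow(nodes))) {
    pmfs <- lapply(fams, function(f)
      xy_pmf(f, nodes[r, 1], nodes[r, 2], muK, beta, gamma, shape, mode))
    names(pmfs) <- fams
    wsum <- 0
    for (k in seq_len(reps)) {
      xs <- sample_pmf(pmfs[[truth]], n_cells,
                       seed = derive_seed(seed, r * 1000L + k))
      ll <- vapply(pmfs, function(p) count_loglik(xs, p), 1)
      w <- akaike_weights(ll, npar = 3L)$weight
      wsum <- wsum + w[match(truth, fams)]
    }
    out$weight[r] <- wsum / reps
  }
  out
}

## ---- capture-ratio posterior ----------------------------------------------

#' Precompute bursty PMFs over a grid of capture-probability ratios
#'
#' The bursty model with Bernoulli capture `(pN, pM)` depends only on
#' `b*pN` and `pM/pN`; following the bookkeeping convention, the larger of
#' the two probabilities is set to 1.
#'
#' @param ratios vector of `pM/pN` values.
#' @param alpha burst frequency; `bpN` identifiable burst-size product;
#'   `muN`, `muM` fixed species means.
#' @param bpN,muN,muM fixed identifiable parameters.
#' @param shape PMF evaluation grid.
#' @return list of `pmf_grid`s, one per ratio.
#' @export
ratio_pmf_table <- function(ratios, alpha = 1, bpN = 4.9, muN = 7, muM = 10,
                            shape = c(40L, 40L)) {
  beta <- alpha * bpN / muN
  lapply(ratios, function(rho) {
    if (rho <= 1) { pN <- 1; pM <- rho } else { pM <- 1; pN <- 1 / rho }
    b <- bpN / pN
    gamma <- alpha * b * pM / muM
    model <- bursty_model(alpha, b, beta, gamma)
    stack <- noise_stack(library = library_noise("sequestering", p = c(pN, pM)))
    gf_to_pmf(model, shape = shape, noise = stack)
  })
}

#' Grid posterior of the capture-probability ratio
#'
#' Evaluates the data likelihood of the bursty model over 200 evenly spaced
#' values of `log10(pM/pN)` on `[-2, 2]` (flat prior; the posterior is each
#' likelihood vector divided by its sum), holding `alpha`, `b*pN`, `muN` and
#' `muM` fixed.
#'
#' @param counts bivariate count matrix.
#' @param alpha,bpN,muN,muM fixed parameters.
#' @param ngrid number of grid points.
#' @param shape PMF grid; default `max(count) + 3` per species.
#' @param table optional precomputed [ratio_pmf_table()] (its grids must
#'   cover the counts).
#' @return list of class `ratio_posterior`: `log10_ratio`, `posterior`
#'   (sums to 1), `logL`, and the posterior mean of `log10(pM/pN)`.
#' @export
ratio_posterior <- function(counts, alpha = 1, bpN = 4.9, muN = 7, muM = 10,
                            ngrid = 200L, shape = NULL, table = NULL) {
  counts <- as.matrix(counts)
  lr <- seq(-2, 2, length.out = ngrid)
  if (is.null(table)) {
    shape <- shape %||% (apply(counts, 2, max) + 4L)
    table <- ratio_pmf_table(10^lr, alpha, bpN, muN, muM, shape)
  } else if (length(table) != ngrid) stop("table length must match ngrid")
  ll <- vapply(table, function(p) count_loglik(counts, p), 1)
  w <- exp(ll - max(ll))
  post <- w / sum(w)
  structure(list(log10_ratio = lr, posterior = post, logL = ll,
                 mean_log10_ratio = sum(lr * post)), class = "ratio_posterior")
}

#' @export
#' @method print ratio_posterior
print.ratio_posterior <- function(x, ...) {
  cat(sprintf("<ratio_posterior: E[log10 pM/pN] = %.3f (sd %.3f) over [-2, 2]>\n",
              x$mean_log10_ratio,
              sqrt(sum((x$log10_ratio - x$mean_log10_ratio)^2 * x$posterior))))
  invisible(x)
}
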