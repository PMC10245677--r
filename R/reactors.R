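## Reactor models of snapshot sampling from transient processes.
##
## Cells enter a tissue ("reactor"), run a transient transcriptional program
## for a time t since entry, and exit after a residence time drawn from a
## reactor-specific law; sequencing samples the cells currently present, so
## observed process times follow the reactor's internal-age distribution
## f(t) = (1/T) * P(residence > t).  Three one-parameter architectures are
## supported: the plug-flow reactor (Dirac residence, uniform ages), the
## continuously stirred tank reactor (exponential residence and ages) and
## the laminar-flow reactor (Pareto residence, uniform-then-power-law ages).

#' Reactor specification
#' @param kind `"pfr"`, `"cstr"` or `"lfr"`.
#' @param T mean residence time (time units, `> 0`).
#' @return object of class `reactor_spec`.
#' @export
reactor_spec <- function(kind = c("pfr", "cstr", "lfr"), T) {
  kind <- match.arg(kind)
  if (!is.numeric(T) || T <= 0) stop("mean residence time T must be positive")
  structure(list(kind = kind, T = T), class = "reactor_spec")
}

#' Internal-age distribution of a reactor
#'
#' Returns the pdf, cdf and inverse cdf of the time-since-entry of cells
#' present at sampling: uniform on `[0, T]` for the PFR, exponential with
#' mean `T` for the CSTR, and for the LFR `f(t) = 1/T` below `T/2` and
#' `T/(4 t^2)` beyond.
#'
#' @param spec a [reactor_spec()].
#' @return list with vectorized functions `pdf`, `cdf`, `icdf`, plus the
#'   support upper end (`Inf` for CSTR/LFR).
#' @export
internal_age <- function(spec) {
  T <- spec$T
  switch(spec$kind,
    pfr = list(
      pdf = function(t) ifelse(t >= 0 & t < T, 1 / T, 0),
      cdf = function(t) pmin(pmax(t / T, 0), 1),
      icdf = function(p) { .check_p(p); p * T },
      upper = T),
    cstr = list(
      pdf = function(t) ifelse(t >= 0, exp(-t / T) / T, 0),
      cdf = function(t) ifelse(t >= 0, 1 - exp(-t / T), 0),
      icdf = function(p) { .check_p(p); -T * log(1 - p) },
      upper = Inf),
    lfr = list(
      pdf = function(t) ifelse(t < 0, 0, ifelse(t < T / 2, 1 / T, T / (4 * t^2))),
      cdf = function(t) ifelse(t < 0, 0, ifelse(t < T / 2, t / T, 1 - T / (4 * t))),
      icdf = function(p) { .check_p(p); ifelse(p < 1 / 2, p * T, T / (4 * (1 - p))) },
      upper = Inf))
}

.check_p <- function(p) {
  if (any(p < 0 | p >= 1)) stop("probabilities must lie in [0, 1)")
}

## Residence-time inverse CDFs (used by the observation-window simulator).
residence_icdf <- function(spec) {
  T <- spec$T
  switch(spec$kind,
    pfr = function(p) rep(T, length(p)),
    cstr = function(p) -T * log(1 - p),
    lfr = function(p) T / (2 * sqrt(1 - p)))
}

#' Quantile-map times between reactor clocks
#'
#' Transforms internal-age times observed under reactor `from` to the
#' corresponding quantiles of reactor `to`:
#' `t_k = F_k^{-1}(F_from(t))`.  The map is rank-preserving and is the
#' identity when both reactors coincide.
#'
#' @param t times within the support of `from`'s internal-age law.
#' @param from,to [reactor_spec()]s.
#' @return transformed times.
#' @export
transform_times <- function(t, from, to) {
  if (identical(from, to)) return(t)
  internal_age(to)$icdf(internal_age(from)$cdf(t))
}

#' Sample cell ages from a reactor
#'
#' Either by inverse-transform sampling of the internal-age cdf
#' (`method = "icdf"`), or by explicit simulation of the observation window:
#' arrivals uniform on `[0, window]`, residence drawn from the reactor's
#' residence law, observation at `at`, retaining cells present at that
#' moment (`method = "window"`).
#'
#' @param spec a [reactor_spec()].
#' @param n number of ages (for `"window"`, the number of *arrivals*
#'   simulated; the returned vector holds the retained cells only).
#' @param seed optional integer seed.
#' @param method `"icdf"` or `"window"`.
#' @param window,at observation-window construction parameters.
#' @return numeric vector of ages.
#' @export
sample_ages <- function(spec, n, seed = NULL, method = c("icdf", "window"),
                        window = 100, at = 75) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "icdf") return(internal_age(spec)$icdf(runif(n)))
  arrive <- runif(n, 0, window)
  res <- residence_icdf(spec)(runif(n))
  keep <- arrive <= at & arrive + res > at
  at - arrive[keep]
}

## ---- transient bursty model ----------------------------------------------

#' Transient bursty-model parameters with a three-stage burst profile
#'
#' Bursty transcription whose geometric burst-size mean steps through
#' `b1 -> b2 -> b3` at deterministic times `tau1 < tau2` (a coarse model of
#' transitions through three cell types).  The initial molecular state is
#' bivariate Poisson with the stage-1 stationary means
#' `lambdaN0 = alpha*b1/beta`, `lambdaM0 = alpha*b1/gamma`, which keeps the
#' mean constant over the first stage.
#'
#' @param b length-3 vector of stage burst means.
#' @param tau length-2 vector of stage-change times (`0 < tau1 < tau2`).
#' @param alpha burst frequency; `beta` splicing rate; `gamma` degradation
#'   rate.
#' @param alpha,beta,gamma rates.
#' @return object of class `transient_params`.
#' @export
transient_params <- function(b, tau, alpha, beta, gamma) {
  if (length(b) != 3 || any(b <= 0)) stop("b must be 3 positive stage means")
  if (length(tau) != 2 || tau[1] <= 0 || tau[2] <= tau[1])
    stop("stage-change times must satisfy 0 < tau1 < tau2")
  .pos(alpha, beta, gamma)
  structure(list(b = b, tau = tau, alpha = alpha, beta = beta, gamma = gamma,
                 lambdaN0 = alpha * b[1] / beta, lambdaM0 = alpha * b[1] / gamma),
            class = "transient_params")
}

#' @export
#' @method print transient_params
print.transient_params <- function(x, ...) {
  cat(sprintf("<transient bursty model: b = (%s) switching at tau = (%s); alpha=%.3g beta=%.3g gamma=%.3g>\n",
              paste(format(x$b, digits = 4), collapse = ", "),
              paste(format(x$tau, digits = 4), collapse = ", "),
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

b_profile <- function(params) {
  function(t) ifelse(t < params$tau[1], params$b[1],
              ifelse(t <= params$tau[2], params$b[2], params$b[3]))
}

## Monomolecular characteristics of the nascent/mature pair (closed form,
## with the beta == gamma limit handled).
UN_char <- function(uN, uM, s, beta, gamma) {
  if (abs(beta - gamma) < 1e-9) {
    uN * exp(-beta * s) + uM * beta * s * exp(-beta * s)
  } else {
    uN * exp(-beta * s) + uM * beta / (beta - gamma) * (exp(-gamma * s) - exp(-beta * s))
  }
}

#' Transient bursty generating function
#'
#' Evaluates the log-GF
#' `lambdaN0 U_N(u,t) + lambdaM0 U_M(u,t) +
#'  alpha * int_0^t [1/(1 - b(t - s) U_N(u,s)) - 1] ds`
#' by panel-wise Gauss-Legendre quadrature split at the burst-profile
#' discontinuities.
#'
#' @param u spectral points: complex matrix with columns `(uN, uM)` (a
#'   length-2 vector is promoted).
#' @param t process time (`>= 0`).
#' @param params a [transient_params()].
#' @param n_nodes Gauss-Legendre nodes per smooth panel.
#' @return complex vector of GF values.
#' @export
transient_gf <- function(u, t, params, n_nodes = 64L) {
  U0 <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  storage.mode(U0) <- "complex"
  if (t < 0) stop("t must be nonnegative")
  bfun <- b_profile(params)
  be <- params$beta; ga <- params$gamma; al <- params$alpha
  UNt <- UN_char(U0[, 1], U0[, 2], t, be, ga)
  UMt <- U0[, 2] * exp(-ga * t)
  lg <- params$lambdaN0 * UNt + params$lambdaM0 * UMt
  if (t > 0) {
    cuts <- sort(unique(c(0, t, t - params$tau)))
    cuts <- cuts[cuts >= 0 & cuts <= t]
    acc <- 0 + 0i
    for (i in seq_len(length(cuts) - 1L)) {
      gl <- pracma::gaussLegendre(n_nodes, cuts[i], cuts[i + 1L])
      for (j in seq_along(gl$x)) {
        s <- gl$x[j]
        z <- bfun(t - s) * UN_char(U0[, 1], U0[, 2], s, be, ga)
        if (any(Mod(1 - z) < 1e-12))
          stop(sprintf("integrand singularity (1 - b U -> 0) at quadrature node s = %.6g", s))
        acc <- acc + gl$w[j] * (z / (1 - z))
      }
    }
    lg <- lg + al * acc
  }
  exp(lg)
}

#' Transient PMF at one process time
#' @param params a [transient_params()]; `t` process time; `shape` grid.
#' @param t process time.
#' @param shape per-species grid sizes (nascent, mature).
#' @param ... passed to [transient_gf()].
#' @return a `pmf_grid`.
#' @export
transient_pmf <- function(params, t, shape, ...) {
  grid <- spectral_grid(shape)
  vals <- transient_gf(grid$u, t, params, ...)
  pmf_from_gf_values(vals, shape)
}

## Shared quadrature nodes: 0 plus the sorted cell times, densified by
## midpoint insertion when fewer than `dense_below` cell times are supplied
## (inserted nodes are quadrature-only, not likelihood points).
quadrature_nodes <- function(times, dense_below = 100L, target = 1025L) {
  s <- sort(unique(c(0, times)))
  if (length(times) >= dense_below) return(s)
  while (length(s) < target) s <- sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
  s
}

#' Quadrature matrices of the batch transient evaluator
#'
#' Exposes the lower-triangular matrix `TQ[i, j] = b(t_i - t_j)` over the
#' shared time grid (Toeplitz on a uniform grid) used by the
#' quadrature-recycling algorithm.
#'
#' @param params a [transient_params()].
#' @param times sorted cell times (0 is prepended).
#' @return list with `s` (grid) and `TQ`.
#' @export
quadrature_matrices <- function(params, times) {
  if (is.unsorted(times)) stop("times must be sorted ascending")
  s <- unique(c(0, times))
  bfun <- b_profile(params)
  TQ <- matrix(0, length(s), length(s))
  for (i in seq_along(s)) TQ[i, seq_len(i)] <- bfun(s[i] - s[seq_len(i)])
  list(s = s, TQ = TQ)
}

#' Batch transient PMFs by quadrature recycling
#'
#' Evaluates the transient distribution at every supplied cell time by
#' reusing the shared time grid as trapezoidal quadrature nodes (one pass
#' over the lower-triangular `b(t_i - t_j) * U_N(u, t_j)` system instead of
#' an independent quadrature per cell).
#'
#' @param params a [transient_params()].
#' @param times sorted ascending cell times.
#' @param shape per-species grid sizes.
#' @return list of `pmf_grid`s, one per time.
#' @export
batch_transient_pmfs <- function(params, times, shape) {
  if (is.unsorted(times)) stop("times must be sorted ascending")
  grid <- spectral_grid(shape)
  uN <- grid$u[, 1]; uM <- grid$u[, 2]
  be <- params$beta; ga <- params$gamma; al <- params$alpha
  s <- quadrature_nodes(times)
  bfun <- b_profile(params)
  npts <- nrow(grid$u)
  UNmat <- matrix(0 + 0i, npts, length(s))
  for (j in seq_along(s)) UNmat[, j] <- UN_char(uN, uM, s[j], be, ga)
  out <- vector("list", length(times))
  for (ci in seq_along(times)) {
    tc <- times[ci]
    jmax <- match(tc, s)
    idx <- seq_len(jmax)
    bv <- bfun(tc - s[idx])
    Z <- sweep(UNmat[, idx, drop = FALSE], 2, bv, `*`)
    if (any(Mod(1 - Z) < 1e-12))
      stop(sprintf("integrand singularity (1 - b U -> 0) for cell time %.6g", tc))
    M <- Z / (1 - Z)
    ## trapezoid along the row grid s[idx]
    if (jmax > 1) {
      w <- diff(s[idx])
      integral <- 0.5 * (M[, -jmax, drop = FALSE] + M[, -1, drop = FALSE]) %*% w
    } else integral <- 0 + 0i
    lg <- params$lambdaN0 * UNmat[, jmax] + params$lambdaM0 * uM * exp(-ga * tc) +
      al * as.vector(integral)
    out[[ci]] <- pmf_from_gf_values(exp(lg), shape)
  }
  out
}

#' Marginalize a time-dependent generating function over a reactor
#'
#' Computes `int G(u, t) f(t) dt` against the reactor's internal-age
#' distribution by Gauss-Legendre quadrature in the probability domain
#' (`t = F^{-1}(p)`, `p` on `[0, 1)`), which handles the CSTR/LFR infinite
#' supports.
#'
#' @param gf function `gf(U, t)` returning complex GF values.
#' @param spec a [reactor_spec()].
#' @param U spectral-point matrix passed through to `gf`.
#' @param n_nodes quadrature nodes.
#' @return complex vector of reactor-marginal GF values.
#' @export
reactor_marginal_gf <- function(gf, spec, U, n_nodes = 128L) {
  age <- internal_age(spec)
  gl <- pracma::gaussLegendre(n_nodes, 0, 1 - 1e-10)
  acc <- 0 + 0i
  for (j in seq_along(gl$x)) {
    acc <- acc + gl$w[j] * gf(U, age$icdf(gl$x[j]))
  }
  acc
}
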