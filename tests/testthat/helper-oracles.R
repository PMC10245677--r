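## Independent oracles used across the suite: dense chemical-master-equation
## generators solved by linear algebra (finite state projection), explicit
## thinning convolutions, and total-variation distance.

tv <- burstgf:::tv_distance

## stationary law of a dense generator Q (rows = from, cols = to)
fsp_stationary <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  qr.solve(A, c(numeric(n), 1))
}

## telegraph model with a single transcript species on counts 0..nmax
telegraph_generator <- function(kon, koff, kinit, gamma, nmax) {
  ns <- 2L * (nmax + 1L)
  ix <- function(g, x) g + 1L + 2L * x  # g = 0 off, 1 on
  Q <- matrix(0, ns, ns)
  for (x in 0:nmax) {
    Q[ix(0L, x), ix(1L, x)] <- kon
    Q[ix(1L, x), ix(0L, x)] <- koff
    if (x < nmax) Q[ix(1L, x), ix(1L, x + 1L)] <- kinit
    if (x > 0) for (g in 0:1) Q[ix(g, x), ix(g, x - 1L)] <- gamma * x
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

telegraph_fsp_marginal <- function(kon, koff, kinit, gamma, nmax) {
  pi_ <- fsp_stationary(telegraph_generator(kon, koff, kinit, gamma, nmax))
  vapply(0:nmax, function(x) pi_[2L * x + 1L] + pi_[2L * x + 2L], 1)
}

## one-species bursty model with geometric bursts on counts 0..nmax
bursty_generator <- function(alpha, b, beta, nmax) {
  n <- nmax + 1L
  Q <- matrix(0, n, n)
  for (x in 0:nmax) {
    if (x > 0) Q[x + 1L, x] <- beta * x
    if (x < nmax) for (k in 1:(nmax - x))
      Q[x + 1L, x + k + 1L] <- alpha * dgeom(k, 1 / (1 + b))
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Bernoulli thinning of a PMF vector (explicit convolution oracle)
thin_pmf <- function(p, prob, nmax = length(p) - 1L) {
  vapply(0:nmax, function(k) sum(dbinom(k, 0:(length(p) - 1L), prob) * p), 1)
}

## empirical PMF of integer draws on 0..(n-1)
empirical_pmf <- function(x, n) tabulate(x + 1L, nbins = n) / length(x)

## empirical joint PMF of count pairs on a grid
empirical_pmf2 <- function(x, shape) {
  tab <- table(factor(x[, 1], levels = 0:(shape[1] - 1L)),
               factor(x[, 2], levels = 0:(shape[2] - 1L)))
  unclass(tab) / sum(tab)
}
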