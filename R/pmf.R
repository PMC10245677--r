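## Generating function -> probability mass function by inverse FFT.
##
## The GF of a discrete law, evaluated at the FFT roots of unity
## g_k = exp(2*pi*i*k/s) per axis, is the (unnormalized) inverse DFT of the
## PMF; the PMF is therefore recovered by the forward FFT divided by the
## grid size.  Continuous species are marginalized by pinning their spectral
## coordinates at zero.

#' Construct a spectral evaluation grid
#'
#' Builds the product grid of shifted unit-circle points `u = g - 1`,
#' `g_k = exp(2*pi*i*k/s_j)`, for the discrete species of a model.
#'
#' @param shape integer vector of per-species grid sizes (state space is
#'   `0..shape-1` per axis).
#' @return an object of class `spectral_grid` with elements `shape`, `g`
#'   (list of per-axis circle points) and `u` (matrix, one row per grid
#'   point, axes varying fastest-first like an R array).
#' @export
spectral_grid <- function(shape) {
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("grid sizes must be positive")
  g <- lapply(shape, function(s) exp(2i * pi * (0:(s - 1)) / s))
  u_ax <- lapply(g, function(gi) gi - 1)
  npts <- prod(shape)
  U <- matrix(0 + 0i, npts, length(shape))
  rep_each <- 1L
  for (j in seq_along(shape)) {
    U[, j] <- rep(rep(u_ax[[j]], each = rep_each), length.out = npts)
    rep_each <- rep_each * shape[j]
  }
  structure(list(shape = shape, g = g, u = U), class = "spectral_grid")
}

#' Pin gene-state coordinates and sum per-state generating functions
#'
#' Marginalizes a per-state GF evaluation over the (unobservable) gene
#' state: the state-wise values are summed, which corresponds to evaluating
#' the gene-state spectral coordinates at zero.  For single-state models
#' this is the identity.
#'
#' @param G complex matrix of per-state GF values (`npts x N`) or a vector.
#' @return complex vector of marginal GF values.
#' @export
marginalize_gene_state <- function(G) {
  if (is.null(dim(G))) return(G)
  rowSums(G)
}

## Default grid shape from model moments: ceil(mu + 4*sigma) + 4 per species
## (falls back to `fallback` when moments are unavailable).
default_shape <- function(model, buffer = 4L, fallback = 64L) {
  mom <- model_moments(model)
  if (is.null(mom)) return(rep(as.integer(fallback), max(model$n, 1L)))
  pmax(8L, as.integer(ceiling(mom$mean + 4 * sqrt(mom$var)) + buffer + 1L))
}

#' First two stationary moments of a model's discrete species
#'
#' Moment formulas for the built-in families, used to size PMF evaluation
#' grids (`ceil(mu + 4 sigma) + buffer`).  Returns `NULL` when no formula is
#' available for the family.
#'
#' @param model a [gf_model][assemble_operators].
#' @return list with `mean` and `var` vectors over the discrete species, or
#'   `NULL`.
#' @export
model_moments <- function(model) {
  p <- model$params
  fam <- model$family
  if (fam == "constitutive") {
    K <- p$K; gam <- p$gamma
    return(list(mean = K / gam, var = K / gam))
  }
  if (fam == "monomolecular") {
    K <- p$K
    rates <- p$rates
    return(list(mean = K / rates, var = K / rates))
  }
  if (fam == "bursty") {
    b <- p$b; al <- p$alpha; be <- p$beta
    if (is.function(b)) b <- max(vapply(seq(0, 100, by = 1), b, 1))
    muN <- al * b / be
    out <- list(mean = muN, var = muN * (1 + b))
    if (model$n == 2L) {
      gam <- p$gamma
      muM <- al * b / gam
      out$mean <- c(muN, muM)
      out$var <- c(muN * (1 + b), muM * (1 + b * be / (be + gam)))
    }
    return(out)
  }
  if (fam %in% c("telegraph", "gou", "cir")) {
    dr <- driver_moments(model)
    be <- p$beta
    muN <- dr$mean / be
    varN <- muN + dr$var / (be * (be + dr$kappa))
    if (model$n == 1L) return(list(mean = muN, var = varN))
    gam <- p$gamma
    muM <- dr$mean / gam
    varM <- muM + dr$var / (gam * (gam + dr$kappa))
    return(list(mean = c(muN, muM), var = c(varN, varM)))
  }
  if (fam == "autocatalytic") {
    shape <- p$alpha / p$q
    scale <- p$q / (p$gamma - p$q)
    if (!is.null(p$b)) {
      ## bursty-autocatalytic: use the closed-form GF mean/variance
      cc <- p$gamma - p$q
      mu <- p$alpha * p$b / cc
      vv <- mu * (1 + p$b + p$q / cc * (1 + p$b))
      return(list(mean = mu, var = vv))
    }
    return(list(mean = shape * scale, var = shape * scale * (1 + scale)))
  }
  NULL
}

## kappa, mean and variance of the stationary transcription-rate driver
driver_moments <- function(model) {
  p <- model$params
  if (model$family == "telegraph") {
    kap <- p$kon + p$koff
    list(kappa = kap,
         mean = p$kon * p$kinit / kap,
         var = p$kon * p$koff * p$kinit^2 / kap^2)
  } else {
    list(kappa = p$kappa, mean = p$a * p$theta / p$kappa,
         var = p$a * p$theta^2 / p$kappa)
  }
}

#' Invert a model's generating function to a probability mass function
#'
#' Evaluates the (optionally noise-composed) generating function at every
#' FFT node of the spectral grid, applies the inverse fast Fourier transform
#' per axis, clips small negative values, and records the normalization
#' defect `|1 - sum|`.  With `t = "stationary"` the characteristics are
#' integrated over a horizon long enough for the slowest rate to relax.
#'
#' @param model a [gf_model][assemble_operators].
#' @param t duration, or `"stationary"`.
#' @param shape grid shape; defaults to [model_moments()]-based sizing when
#'   available (`ceil(mu + 4 sigma) + buffer`).
#' @param noise optional [noise_stack()] composed onto the model GF.
#' @param buffer grid-sizing buffer added beyond `mu + 4 sigma`.
#' @param neg_tol negatives larger in magnitude than this trigger a warning
#'   recommending a larger grid/tighter solve; smaller ones are clipped.
#' @param warn warn when the grid appears to truncate the support (mass on
#'   the outermost slice above 1e-2, or normalization defect above 1e-3)?
#' @param ... passed to the GF evaluator (`rtol`, `atol`, `n_per_panel`).
#' @return an object of class `pmf_grid`: a numeric array with attributes
#'   `normalization_defect` and `shape`.
#' @examples
#' m <- constitutive_model(K = 2, gamma = 1)
#' p <- gf_to_pmf(m, shape = 32)
#' p[1:3]  # dpois(0:2, 2)
#' @export
gf_to_pmf <- function(model, t = "stationary", shape = NULL, noise = NULL,
                      buffer = 4L, neg_tol = 1e-7, warn = TRUE, ...) {
  shape <- as.integer(shape %||% default_shape(model, buffer))
  base_gf <- function(U) gf_eval(model, U, t = t, ...)
  gf <- if (is.null(noise)) {
    nsp <- max(model$n, 1L)
    if (length(shape) != nsp) stop("grid shape must have one entry per discrete species")
    function(U) {
      Ufull <- cbind(U, matrix(0 + 0i, nrow(U), model$m))
      base_gf(Ufull)
    }
  } else {
    composed_gf(model, noise, t = t, ...)
  }
  grid <- spectral_grid(shape)
  vals <- gf(grid$u)
  pmf_from_gf_values(vals, shape, neg_tol = neg_tol, warn = warn)
}

## Shared FFT inversion / clipping / bookkeeping.  The inverse DFT wraps any
## mass beyond the grid back onto it (it cannot be "lost"), so truncation is
## diagnosed from the mass sitting on the outermost slice of each axis
## rather than from |1 - sum| alone.
pmf_from_gf_values <- function(vals, shape, neg_tol = 1e-7, warn = TRUE) {
  arr <- array(vals, dim = shape)
  P <- Re(fft(arr)) / prod(shape)
  neg <- min(P)
  if (neg < -neg_tol)
    warning(sprintf(paste0("PMF has negative mass down to %.3g; ",
                           "increase the grid size or solver accuracy"), neg))
  P[P < 0] <- 0
  defect <- abs(1 - sum(P))
  if (warn) {
    edge <- max(vapply(seq_along(shape), function(j) {
      marg <- if (length(shape) == 1L) P else apply(P, j, sum)
      marg[shape[j]]
    }, 1))
    if (defect > 1e-3 || edge > 1e-2)
      warning(sprintf(paste0("the grid likely truncates the support ",
                             "(defect %.3g, boundary mass %.3g); ",
                             "a larger grid is recommended"), defect, edge))
  }
  structure(P, shape = shape, normalization_defect = defect, class = "pmf_grid")
}

#' @export
#' @method print pmf_grid
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid %s; mass %.6f; normalization defect %.2e>\n",
              paste(attr(x, "shape"), collapse = " x "),
              sum(x), attr(x, "normalization_defect")))
  invisible(x)
}

#' Marginal of a multi-species PMF grid
#' @param pmf a `pmf_grid` (or plain array).
#' @param axis which species axis to keep.
#' @return numeric vector of marginal probabilities.
#' @export
pmf_marginal <- function(pmf, axis = 1L) {
  d <- dim(pmf) %||% length(pmf)
  if (length(d) == 1L) return(as.numeric(pmf))
  apply(unclass(pmf), axis, sum)
}

#' Means/covariance implied by a PMF grid
#' @param pmf a `pmf_grid`.
#' @return list with `mean` vector and `cov` matrix over species.
#' @export
pmf_moments <- function(pmf) {
  d <- dim(pmf) %||% length(pmf)
  P <- unclass(pmf) / sum(pmf)
  if (length(d) == 1L) {
    x <- seq_len(length(P)) - 1
    mu <- sum(x * P)
    return(list(mean = mu, cov = matrix(sum((x - mu)^2 * P), 1, 1)))
  }
  k <- length(d)
  sup <- lapply(d, function(s) seq_len(s) - 1)
  mu <- numeric(k)
  for (j in seq_len(k)) mu[j] <- sum(apply(P, j, sum) * sup[[j]])
  cv <- matrix(0, k, k)
  grid <- as.matrix(expand.grid(sup))
  pv <- as.vector(P)
  for (a in seq_len(k)) for (b in seq_len(k))
    cv[a, b] <- sum((grid[, a] - mu[a]) * (grid[, b] - mu[b]) * pv)
  list(mean = mu, cov = cv)
}

#' Draw count vectors from a PMF grid
#'
#' I.i.d. categorical sampling over the flattened truncated state space.
#'
#' @param pmf a `pmf_grid`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param tol maximum tolerated normalization defect.
#' @return integer matrix `n x n_species` of counts.
#' @export
sample_pmf <- function(pmf, n, seed = NULL, tol = 1e-2) {
  defect <- abs(1 - sum(pmf))
  if (defect > tol)
    stop(sprintf("PMF is unnormalized beyond tolerance (defect %.3g)", defect))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(pmf) %||% length(pmf)
  p <- as.vector(pmf) / sum(pmf)
  ix <- sample.int(length(p), n, replace = TRUE, prob = p) - 1L
  out <- matrix(0L, n, length(d))
  for (j in seq_along(d)) {
    out[, j] <- as.integer(ix %% d[j])
    ix <- ix %/% d[j]
  }
  colnames(out) <- paste0("x", seq_along(d))
  out
}

## Total-variation distance between two (possibly differently shaped) PMFs;
## arrays are zero-padded into a common shape before comparison.
tv_distance <- function(p, q) {
  dp <- dim(p) %||% length(p)
  dq <- dim(q) %||% length(q)
  if (length(dp) != length(dq)) stop("PMF dimensionalities differ")
  d <- pmax(dp, dq)
  pad <- function(x, dx) {
    out <- array(0, d)
    ix <- lapply(dx, seq_len)
    out[as.matrix(expand.grid(ix))] <- as.vector(unclass(x))
    out
  }
  0.5 * sum(abs(pad(p, dp) - pad(q, dq)))
}
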