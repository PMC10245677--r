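## Composable technical-noise transforms for droplet scRNA-seq.
##
## The observed-count generating function is the composition
##     G_obs(u) = [G_enc(G_cell) * G_bg] (G_t*(G_a*(u))),
## where G_enc is the per-droplet cell-number PGF (Bernoulli / binomial /
## Poisson), G_bg = exp(c * sum_i mu_i u_i) the independent-Poisson ambient
## background, G_t* the per-molecule library-construction substitution
## (sequestering u_i -> p_i u_i; non-sequestering u_i -> exp(lambda_i u_i) - 1),
## and G_a* the row-stochastic read-ambiguity coordinate transform
## u_source = P_a %*% u_observed.  Ambiguity is applied innermost (closest to
## the observed coordinates).

#' Droplet encapsulation specification
#' @param scheme `"bernoulli"` (0 or 1 cells), `"binomial"` (0-2 cells from
#'   two independent tries), or `"poisson"` (unconstrained cell number).
#' @param p single-cell capture probability (bernoulli/binomial schemes).
#' @param lambda per-droplet cell rate (poisson scheme).
#' @return object of class `encapsulation_spec`.
#' @export
encapsulation_spec <- function(scheme = c("bernoulli", "binomial", "poisson"),
                               p = NULL, lambda = NULL) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("bernoulli", "binomial")) {
    if (is.null(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  } else if (is.null(lambda) || lambda < 0) stop("lambda must be nonnegative")
  structure(list(scheme = scheme, p = p, lambda = lambda),
            class = "encapsulation_spec")
}

#' Compose an encapsulation transform onto a cell generating function
#'
#' Returns the per-droplet GF of total cellular RNA: `p*G + (1 - p)`
#' (bernoulli), `(p*G + (1 - p))^2` (binomial), or `exp(lambda*(G - 1))`
#' (poisson).
#'
#' @param spec an [encapsulation_spec()].
#' @param G a GF evaluator (function of a spectral-point matrix) or a vector
#'   of GF values.
#' @return matching evaluator (or vector) of droplet-level GF values.
#' @export
encapsulation_gf <- function(spec, G) {
  f <- switch(spec$scheme,
    bernoulli = function(g) spec$p * g + (1 - spec$p),
    binomial = function(g) (spec$p * g + (1 - spec$p))^2,
    poisson = function(g) exp(spec$lambda * (g - 1)))
  if (is.function(G)) function(...) f(G(...)) else f(G)
}

#' Ambient background specification
#' @param c dimensionless pool-size/diffusion constant (`>= 0`).
#' @param mu per-species ambient mean vector (defaults to the composed
#'   model's stationary means when used inside [noise_stack()]).
#' @return object of class `background_spec`.
#' @export
background_spec <- function(c, mu = NULL) {
  if (c < 0) stop("c must be nonnegative")
  if (!is.null(mu) && any(mu < 0)) stop("mu must be nonnegative")
  structure(list(c = c, mu = mu), class = "background_spec")
}

#' Background generating function
#'
#' Independent Poisson debris per species: `G_bg(u) = exp(c * sum_i mu_i u_i)`.
#'
#' @param spec a [background_spec()] (its `mu` must be set).
#' @return function mapping a spectral-point matrix to complex GF values.
#' @export
background_gf <- function(spec) {
  mu <- spec$mu
  if (is.null(mu)) stop("background mu is unset")
  function(U) exp(spec$c * as.vector(U %*% mu))
}

#' Per-species library-construction noise
#'
#' @param mode per-species `"sequestering"` (each RNA templates at most one
#'   UMI-tagged cDNA; Bernoulli retention `p`) or `"non_sequestering"`
#'   (catalytic cDNA synthesis; Poisson rate `lambda`).  Recycled to the
#'   number of species.
#' @param p,lambda per-species retention probabilities / capture rates.
#' @return object of class `library_noise`.
#' @export
library_noise <- function(mode = "sequestering", p = NULL, lambda = NULL) {
  n <- max(length(p), length(lambda), length(mode))
  mode <- rep(mode, length.out = n)
  bad <- !mode %in% c("sequestering", "non_sequestering")
  if (any(bad)) stop("modes must be 'sequestering' or 'non_sequestering'")
  p <- if (!is.null(p)) rep(p, length.out = n)
  lambda <- if (!is.null(lambda)) rep(lambda, length.out = n)
  if (any(mode == "sequestering") && (is.null(p) || any(p[mode == "sequestering"] < 0 | p[mode == "sequestering"] > 1)))
    stop("sequestering noise needs p in [0, 1]")
  if (any(mode == "non_sequestering") && (is.null(lambda) || any(lambda[mode == "non_sequestering"] < 0)))
    stop("non-sequestering noise needs lambda >= 0")
  structure(list(mode = mode, p = p, lambda = lambda, n = n), class = "library_noise")
}

#' Library-construction spectral substitution
#'
#' Maps observed spectral coordinates to the per-molecule shifted GF:
#' `u_i -> p_i u_i` (sequestering) or `u_i -> exp(lambda_i u_i) - 1`
#' (non-sequestering).  Composing this substitution with any model GF gives
#' the observed-count GF.
#'
#' @param noise a [library_noise()].
#' @param U spectral-point matrix (one column per species).
#' @return transformed spectral-point matrix.
#' @export
library_gf <- function(noise, U) {
  if (ncol(U) != noise$n) stop("library noise dimensionality mismatch")
  for (i in seq_len(noise$n)) {
    U[, i] <- if (noise$mode[i] == "sequestering") noise$p[i] * U[, i]
              else exp(noise$lambda[i] * U[, i]) - 1
  }
  U
}

#' Read-identity ambiguity matrix
#'
#' Row `i` of `P` gives the categorical law of how a molecule of source
#' species `i` is parsed among the observable classes (columns); every row
#' must sum to 1.
#'
#' @param P nonnegative `n x n_bar` matrix with unit row sums.
#' @return object of class `ambiguity_matrix`.
#' @export
ambiguity_matrix <- function(P) {
  P <- as.matrix(P)
  if (any(P < 0) || any(P > 1) || any(abs(rowSums(P) - 1) > 1e-10))
    stop("ambiguity matrix rows must be probability vectors summing to 1")
  structure(P, class = c("ambiguity_matrix", "matrix"))
}

#' Ambiguity coordinate transform
#'
#' Maps observed-class spectral points to source-species spectral points:
#' `u_source = P %*% u_observed` (in shifted coordinates).  Collapsing all
#' classes into one (an all-ones column) quantifies total RNA content only.
#'
#' @param P an [ambiguity_matrix()].
#' @param U observed-class spectral-point matrix (`npts x n_bar`).
#' @return source-species spectral-point matrix (`npts x n`).
#' @export
ambiguity_transform <- function(P, U) {
  if (ncol(U) != ncol(P)) stop("observed-class dimensionality mismatch")
  U %*% t(unclass(P))
}

#' Bundle technical-noise components
#'
#' @param encapsulation optional [encapsulation_spec()].
#' @param background optional [background_spec()].
#' @param library optional [library_noise()].
#' @param ambiguity optional [ambiguity_matrix()].
#' @return object of class `noise_stack`; omitted components default to the
#'   identity.
#' @export
noise_stack <- function(encapsulation = NULL, background = NULL,
                        library = NULL, ambiguity = NULL) {
  structure(list(encapsulation = encapsulation, background = background,
                 library = library, ambiguity = ambiguity),
            class = "noise_stack")
}

#' Compose a full observed-count generating function
#'
#' Implements `G_obs = [G_enc(G) * G_bg] o G_t* o G_a*` with identity
#' defaults for omitted stages.
#'
#' @param gf cell-level GF evaluator: function of an `npts x n` spectral
#'   matrix returning complex values.
#' @param stack a [noise_stack()].
#' @param n_species number of source species `n` (for dimension checks).
#' @return function of an `npts x n_bar` observed-class spectral matrix.
#' @export
compose_full <- function(gf, stack, n_species) {
  amb <- stack$ambiguity
  lib <- stack$library
  enc <- stack$encapsulation
  bg <- stack$background
  if (!is.null(lib) && lib$n != n_species)
    stop("library noise dimension does not match the model")
  if (!is.null(amb) && nrow(amb) != n_species)
    stop("ambiguity matrix rows must match the model species")
  function(U) {
    if (!is.null(amb)) U <- ambiguity_transform(amb, U)
    if (ncol(U) != n_species) stop("observed-coordinate dimension mismatch")
    if (!is.null(lib)) U <- library_gf(lib, U)
    G <- gf(U)
    if (!is.null(enc)) G <- encapsulation_gf(enc, G)
    if (!is.null(bg)) G <- G * background_gf(bg)(U)
    G
  }
}

## Observed-count GF of a model under a noise stack; background means default
## to the model's stationary means (pseudobulk assumption).
composed_gf <- function(model, stack, t = "stationary", ...) {
  if (!is.null(stack$background) && is.null(stack$background$mu)) {
    mom <- model_moments(model)
    if (is.null(mom)) stop("background mu must be supplied for this family")
    stack$background$mu <- mom$mean
  }
  cell_gf <- function(U) {
    Ufull <- cbind(U, matrix(0 + 0i, nrow(U), model$m))
    gf_eval(model, Ufull, t = t, ...)
  }
  compose_full(cell_gf, stack, n_species = model$n)
}
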