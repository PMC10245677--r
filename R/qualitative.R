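## The (x, y) qualitative parametrization of transcriptional drivers.
##
## x = kappa/(kappa + beta + gamma) is the timescale separation (one-species
## models replace beta + gamma by beta); y = theta/(a + theta) is the noise
## intensity.  Both live in (0, 1): the bottom edge of the square is the
## Poisson limit, the top-left corner the slow Poisson-mixture regime, the
## top-right the bursty regime.  For the telegraph process the driver is
## identified with the SDE parametrization through
##   kappa = kon + koff,  a = kon*kappa/koff,  theta = koff*kinit/kappa,
## which matches the autocorrelation timescale, mean a*theta/kappa and
## variance theta*muK of the SDE drivers.

.rate_sum <- function(beta, gamma, species) {
  if (species == "one") beta else beta + gamma
}

#' Map process parameters to qualitative coordinates
#'
#' @param params named list: either SDE-driver parameters
#'   (`kappa`, `a`, `theta`) or telegraph rates (`kon`, `koff`, `kinit`),
#'   plus the downstream `beta` (and `gamma` for two-species models).
#' @param species `"two"` (x uses `beta + gamma`) or `"one"` (uses `beta`).
#' @return list with `x`, `y`, `muK` and the identified driver parameters
#'   `kappa`, `a`, `theta`.
#' @examples
#' process_to_qualitative(list(kappa = 0.1, a = 0.4, theta = 1, beta = 0.8),
#'                        species = "one")  # x = 1/9, y = 5/7
#' @export
process_to_qualitative <- function(params, species = c("two", "one")) {
  species <- match.arg(species)
  p <- params
  if (!is.null(p$kon)) {
    kappa <- p$kon + p$koff
    a <- p$kon * kappa / p$koff
    theta <- p$koff * p$kinit / kappa
  } else {
    kappa <- p$kappa; a <- p$a; theta <- p$theta
  }
  denom <- kappa + .rate_sum(p$beta, p$gamma, species)
  list(x = kappa / denom, y = theta / (a + theta), muK = a * theta / kappa,
       kappa = kappa, a = a, theta = theta)
}

#' Map qualitative coordinates to process parameters
#'
#' Inverts the (x, y) construction at fixed averages: given the timescale
#' separation `x`, noise intensity `y`, mean transcription rate `muK` and
#' the downstream rates, recovers `kappa = (beta + gamma) x/(1 - x)` (or
#' `beta x/(1 - x)` in one-species mode) and the driver parameters.  For
#' the SDE families this solves `a/theta = 1/y - 1`, `a*theta = muK*kappa`;
#' for the telegraph family it solves `c = (kon/koff)^2 = (1/y - 1) *
#' muK/kappa` and takes the positive root.  The construction is bijective
#' and round-trips with [process_to_qualitative()].
#'
#' @param x,y qualitative coordinates in (0, 1).
#' @param muK mean transcription rate.
#' @param beta,gamma downstream rates (`gamma` ignored in one-species mode).
#' @param family `"gou"`, `"cir"` or `"telegraph"`.
#' @param species `"two"` or `"one"`.
#' @return named list of process parameters (including `beta`, `gamma`).
#' @export
qualitative_to_process <- function(x, y, muK, beta, gamma = NULL,
                                   family = c("gou", "cir", "telegraph"),
                                   species = c("two", "one")) {
  family <- match.arg(family)
  species <- match.arg(species)
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1)
    stop("x and y must lie strictly inside (0, 1)")
  kappa <- .rate_sum(beta, gamma, species) * x / (1 - x)
  r <- 1 / y - 1                      # a/theta
  if (family == "telegraph") {
    cc <- r * muK / kappa             # (kon/koff)^2; positive root taken
    s <- sqrt(cc)
    kon <- kappa * s / (1 + s)
    koff <- kappa / (1 + s)
    kinit <- muK * kappa / kon
    return(list(kon = kon, koff = koff, kinit = kinit, beta = beta,
                gamma = gamma, kappa = kappa, species = species))
  }
  theta <- sqrt(muK * kappa / r)
  a <- r * theta
  list(kappa = kappa, a = a, theta = theta, beta = beta, gamma = gamma,
       species = species)
}

#' Build a driver-family model at qualitative coordinates
#'
#' @inheritParams qualitative_to_process
#' @return a `gf_model` of the requested family.
#' @export
model_at_xy <- function(x, y, muK, beta, gamma = NULL,
                        family = c("gou", "cir", "telegraph"),
                        species = c("two", "one")) {
  family <- match.arg(family)
  species <- match.arg(species)
  p <- qualitative_to_process(x, y, muK, beta, gamma, family, species)
  if (family == "telegraph")
    telegraph_model(p$kon, p$koff, p$kinit, beta, gamma, species = species)
  else if (family == "gou")
    gou_model(p$kappa, p$a, p$theta, beta, gamma, species = species)
  else
    cir_model(p$kappa, p$a, p$theta, beta, gamma, species = species)
}

#' Reparametrize a driver model for Bernoulli dropout
#'
#' A Bernoulli observation model in which each molecule is observed with
#' probability `p` leaves the functional form of these models' stationary
#' distributions closed: the observed-count law equals the noise-free law
#' of a reparametrized process with `theta -> p*theta` (gamma-OU, CIR) or
#' `kinit -> p*kinit` (telegraph).  The returned parameter set carries the
#' noise-intensity value `y_star` obtained when the dropout is compensated
#' to hold the species averages constant (`a -> a/p`), and the uncompensated
#' value `y_dropped`.
#'
#' @param params named process-parameter list (as from
#'   [qualitative_to_process()]).
#' @param p observation probability in (0, 1].
#' @return the reparametrized parameter list with attributes `y_star` and
#'   `y_dropped`.
#' @export
apply_dropout_closure <- function(params, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  out <- params
  if (!is.null(params$kon)) {
    out$kinit <- params$kinit * p
    kap <- params$kon + params$koff
    a <- params$kon * kap / params$koff
    theta <- params$koff * params$kinit / kap
  } else {
    out$theta <- params$theta * p
    a <- params$a
    theta <- params$theta
  }
  attr(out, "y_star") <- p * theta / (a / p + p * theta)
  attr(out, "y_dropped") <- p * theta / (a + p * theta)
  out
}
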