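## Concrete transcription-model builders.
##
## All builders return a `gf_model` whose H, C, D and burst/drift operator
## match the standard forms of the constitutive, monomolecular, telegraph,
## gamma Ornstein-Uhlenbeck (gamma-OU), Cox-Ingersoll-Ross (CIR), bursty and
## autocatalytic families, plus two-gene co-regulation motifs.  Downstream
## of the transcriptional driver, nascent RNA is spliced at rate beta and
## mature RNA degraded at rate gamma.

.pos <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all rates must be strictly positive", call. = FALSE)
  invisible(v)
}

#' Constitutive (Poisson) transcription model
#' @param K constant transcription rate.
#' @param gamma degradation rate.
#' @return a `gf_model` (N = 1, n = 1).
#' @export
constitutive_model <- function(K, gamma) {
  .pos(K, gamma)
  assemble_operators(list(rxn_produce("X", K), rxn_degrade("X", gamma)),
                     discrete = "X",
                     params = list(K = K, gamma = gamma), family = "constitutive")
}

#' Constitutive two-species (nascent/mature) model
#' @param K transcription rate; `beta` splicing rate; `gamma` degradation
#'   rate.
#' @param beta,gamma downstream rates.
#' @return a `gf_model` (N = 1, n = 2).
#' @export
monomolecular_model <- function(K, beta, gamma) {
  .pos(K, beta, gamma)
  assemble_operators(list(rxn_produce("N", K), rxn_convert("N", "M", beta),
                          rxn_degrade("M", gamma)),
                     discrete = c("N", "M"),
                     params = list(K = K, rates = c(beta, gamma), beta = beta,
                                   gamma = gamma),
                     family = "monomolecular")
}

#' Telegraph (two-state) transcription model
#'
#' Gene switches between an off and an on state; initiation at rate `kinit`
#' occurs only in the on state.  With `species = "two"` the transcript is
#' spliced (rate `beta`) before degradation (rate `gamma`); with
#' `species = "one"` a single transcript species degrades at rate `beta`.
#'
#' @param kon,koff switching rates; `kinit` initiation rate.
#' @param kinit initiation rate in the on state.
#' @param beta splicing rate (or turnover rate in one-species mode).
#' @param gamma degradation rate (two-species mode).
#' @return a `gf_model` (N = 2; state 1 = off, state 2 = on).
#' @export
telegraph_model <- function(kon, koff, kinit, beta, gamma = NULL,
                            species = c("two", "one")) {
  species <- match.arg(species)
  if (species == "two") .pos(kon, koff, kinit, beta, gamma) else .pos(kon, koff, kinit, beta)
  rx <- list(rxn_switch(1, 2, kon), rxn_switch(2, 1, koff),
             rxn_produce("N", kinit, state = 2L))
  disc <- "N"
  if (species == "two") {
    rx <- c(rx, list(rxn_convert("N", "M", beta), rxn_degrade("M", gamma)))
    disc <- c("N", "M")
  } else {
    rx <- c(rx, list(rxn_degrade("N", beta)))
  }
  assemble_operators(rx, discrete = disc, n_states = 2L,
                     params = list(kon = kon, koff = koff, kinit = kinit,
                                   beta = beta, gamma = gamma, species = species),
                     family = "telegraph")
}

#' Gamma Ornstein-Uhlenbeck transcription-rate model
#'
#' The transcription rate is a jump-driven OU process: mean reversion at
#' rate `kappa` and a compound-Poisson subordinator with arrival rate `a`
#' and exponentially distributed jumps of mean `theta`.  Its stationary law
#' is gamma with shape `a/kappa` and scale `theta`.
#'
#' @param kappa mean-reversion rate; `a` jump arrival rate; `theta` jump
#'   mean.
#' @param a,theta driver parameters.
#' @param beta,gamma downstream rates (see [telegraph_model()] for the
#'   one-species convention).
#' @param species `"two"` (nascent + mature) or `"one"`.
#' @return a `gf_model` (N = 1, n = 1 or 2, m = 1).
#' @export
gou_model <- function(kappa, a, theta, beta, gamma = NULL, species = c("two", "one")) {
  species <- match.arg(species)
  if (species == "two") .pos(kappa, a, theta, beta, gamma) else .pos(kappa, a, theta, beta)
  rx <- list(rxn_degrade("K", kappa), rxn_jump("K", a, theta), rxn_drive("K", "N", 1))
  disc <- "N"
  if (species == "two") {
    rx <- c(rx, list(rxn_convert("N", "M", beta), rxn_degrade("M", gamma)))
    disc <- c("N", "M")
  } else {
    rx <- c(rx, list(rxn_degrade("N", beta)))
  }
  assemble_operators(rx, discrete = disc, continuous = "K",
                     params = list(kappa = kappa, a = a, theta = theta,
                                   beta = beta, gamma = gamma, species = species),
                     family = "gou")
}

#' Cox-Ingersoll-Ross transcription-rate model
#'
#' The transcription rate follows the square-root diffusion
#' `dy = (a*theta - kappa*y) dt + sqrt(2*kappa*theta*y) dW`, sharing the
#' gamma(a/kappa, theta) stationary law with the gamma-OU process.
#'
#' @inheritParams gou_model
#' @return a `gf_model` with a quadratic (Riccati) characteristic.
#' @export
cir_model <- function(kappa, a, theta, beta, gamma = NULL, species = c("two", "one")) {
  species <- match.arg(species)
  if (species == "two") .pos(kappa, a, theta, beta, gamma) else .pos(kappa, a, theta, beta)
  rx <- list(rxn_degrade("K", kappa), rxn_drift("K", a * theta),
             rxn_sqrt_noise("K", sqrt(2 * kappa * theta)), rxn_drive("K", "N", 1))
  disc <- "N"
  if (species == "two") {
    rx <- c(rx, list(rxn_convert("N", "M", beta), rxn_degrade("M", gamma)))
    disc <- c("N", "M")
  } else {
    rx <- c(rx, list(rxn_degrade("N", beta)))
  }
  assemble_operators(rx, discrete = disc, continuous = "K",
                     params = list(kappa = kappa, a = a, theta = theta,
                                   beta = beta, gamma = gamma, species = species),
                     family = "cir")
}

#' Bursty transcription model
#'
#' Transcription occurs in bursts arriving at frequency `alpha` with
#' geometric sizes (support 0, 1, 2, ...) of mean `b`; `b` may be a function
#' of process time for transient models.
#'
#' @param alpha burst frequency.
#' @param b mean burst size (number or function of process time).
#' @param beta splicing (or turnover, one-species) rate.
#' @param gamma degradation rate (two-species mode).
#' @param species `"two"` or `"one"`.
#' @return a `gf_model` (N = 1).
#' @export
bursty_model <- function(alpha, b, beta, gamma = NULL, species = c("two", "one")) {
  species <- match.arg(species)
  if (!is.function(b)) .pos(b)
  if (species == "two") .pos(alpha, beta, gamma) else .pos(alpha, beta)
  rx <- list(rxn_burst("N", alpha, b))
  disc <- "N"
  if (species == "two") {
    rx <- c(rx, list(rxn_convert("N", "M", beta), rxn_degrade("M", gamma)))
    disc <- c("N", "M")
  } else {
    rx <- c(rx, list(rxn_degrade("N", beta)))
  }
  assemble_operators(rx, discrete = disc,
                     params = list(alpha = alpha, b = b, beta = beta,
                                   gamma = gamma, species = species),
                     family = "bursty")
}

#' Autocatalytic transcription model
#'
#' Constitutive production at rate `alpha` (or geometric bursts of mean `b`
#' when given), autocatalysis `X -> 2X` at rate `q`, degradation at rate
#' `gamma`.  Stationarity requires `gamma > q` (and `b*(gamma - q) > q` for
#' the bursty variant).
#'
#' @param alpha production rate; `q` autocatalysis rate; `gamma` degradation.
#' @param q,gamma rates.
#' @param b optional mean geometric burst size.
#' @return a `gf_model` (N = 1, n = 1) with `D != 0`.
#' @export
autocatalytic_model <- function(alpha, q, gamma, b = NULL) {
  .pos(alpha, q, gamma)
  if (gamma <= q) stop("stationarity requires gamma > q")
  if (!is.null(b)) {
    .pos(b)
    if (b * (gamma - q) <= q) stop("stationarity requires b*(gamma - q) > q")
  }
  rx <- list(if (is.null(b)) rxn_produce("X", alpha) else rxn_burst("X", alpha, b),
             rxn_degrade("X", gamma), rxn_catalyze("X", "X", q))
  assemble_operators(rx, discrete = "X",
                     params = list(alpha = alpha, q = q, gamma = gamma, b = b),
                     family = "autocatalytic")
}

#' Build a model from a parameter object or family name
#'
#' Dispatch helper: `build_model("telegraph", list(kon = 1, ...))` is
#' equivalent to calling the family builder directly.
#'
#' @param family one of `"constitutive"`, `"monomolecular"`, `"telegraph"`,
#'   `"gou"`, `"cir"`, `"bursty"`, `"autocatalytic"`.
#' @param params named list of the family's parameters.
#' @return a `gf_model`.
#' @export
build_model <- function(family, params) {
  builder <- switch(family,
    constitutive = constitutive_model, monomolecular = monomolecular_model,
    telegraph = telegraph_model, gou = gou_model, cir = cir_model,
    bursty = bursty_model, autocatalytic = autocatalytic_model,
    stop(sprintf("unknown model family '%s'", family)))
  do.call(builder, params)
}

## ---- closed-form stationary laws ------------------------------------------

#' Closed-form stationary law of a model family
#'
#' Returns the analytic stationary distribution where one exists:
#' constitutive (Poisson), one-species bursty (negative binomial),
#' autocatalytic (negative binomial), telegraph in the slow-switching limit
#' (scaled-Bernoulli Poisson mixture), and the slow gamma-driver limit
#' (bivariate negative binomial mixture).  Families without a closed form
#' signal a condition of class `"no_closed_form"`.
#'
#' @param family family name (see Details) or a `gf_model`.
#' @param params named parameter list (ignored when `family` is a model).
#' @return a list of class `closed_form` with the law's `type`, parameters,
#'   and a `dpmf(x, ...)` evaluator over counts.
#' @export
stationary_closed_form <- function(family, params = NULL) {
  if (inherits(family, "gf_model")) {
    params <- family$params
    family <- family$family
  }
  p <- params
  law <- switch(family,
    constitutive = {
      lam <- p$K / p$gamma
      list(type = "poisson", lambda = lam, dpmf = function(x) dpois(x, lam))
    },
    bursty = {
      shape <- p$alpha / p$beta
      scale <- p$b
      list(type = "negative_binomial", shape = shape, scale = scale,
           dpmf = function(x) dnbinom(x, size = shape, prob = 1 / (1 + scale)))
    },
    autocatalytic = {
      if (!is.null(p$b)) stop_no_closed_form("bursty autocatalytic counts follow an NB-NB mixture; use bursty_autocat_gf()")
      shape <- p$alpha / p$q
      scale <- p$q / (p$gamma - p$q)
      list(type = "negative_binomial", shape = shape, scale = scale,
           dpmf = function(x) dnbinom(x, size = shape, prob = 1 / (1 + scale)))
    },
    telegraph_mixture = {
      ## slow-switching limit: Poisson mixture of the scaled Bernoulli driver
      kap <- p$kon + p$koff
      lam <- p$kinit / p$beta
      list(type = "poisson_mixture", weights = c(p$koff, p$kon) / kap,
           lambda = c(0, lam),
           dpmf = function(x) (p$koff * dpois(x, 0) + p$kon * dpois(x, lam)) / kap)
    },
    gamma_mixture = {
      ## slow gamma-driver limit: bivariate NB (eq. GF (1 - th uN/beta - th uM/gamma)^(-v))
      v <- p$a / p$kappa
      list(type = "bivariate_negative_binomial", shape = v,
           scaleN = p$theta / p$beta, scaleM = if (!is.null(p$gamma)) p$theta / p$gamma else NULL,
           dpmf = function(x) {
             sc <- p$theta / p$beta
             dnbinom(x, size = v, prob = 1 / (1 + sc))
           })
    },
    stop_no_closed_form(family))
  structure(c(law, list(family = family, params = p)), class = "closed_form")
}

stop_no_closed_form <- function(family) {
  stop(structure(class = c("no_closed_form", "error", "condition"),
                 list(message = sprintf("no closed-form stationary law for '%s'", family),
                      call = sys.call(-1))))
}

#' Closed-form generating function of the bursty autocatalytic model
#'
#' `G(u) = ((1 - (q/c) u)/(1 - b u))^v` with `c = gamma - q` and
#' `v = alpha*b/(b*c - q)`.  Under the substitution `q/c = b exp(-kappa*tau)`
#' this equals the transient generating function of bursty transcription
#' with no autocatalysis.
#'
#' @param alpha,q,gamma,b model parameters (`b*(gamma - q) > q`).
#' @return a function `G(u)` over (vectors of) shifted spectral points.
#' @export
bursty_autocat_gf <- function(alpha, q, gamma, b) {
  .pos(alpha, q, gamma, b)
  cc <- gamma - q
  if (b * cc <= q) stop("stationarity requires b*(gamma - q) > q")
  v <- alpha * b / (b * cc - q)
  function(u) ((1 - (q / cc) * u) / (1 - b * u))^v
}

## ---- coupled two-gene models ----------------------------------------------

#' Two-gene co-regulation and mixture models
#'
#' Builds one of the coupling motifs for two genes with transcript species
#' `x1`, `x2` degraded at rates `gamma1`, `gamma2`:
#' * `"mixture"`: cell-type mixture `sum_k pi_k prod_j G_j(u_j; theta_k)` —
#'   returns a GF evaluator over the two spectral coordinates;
#' * `"state_coupled"`: the symmetric N = 4 chain (both-off / one-on /
#'   both-on) whose intermediate-state stability is controlled by `epsilon`
#'   (`epsilon = 1` recovers independent telegraph genes);
#' * `"cobursting_n2"`: the fast-intermediate (`epsilon -> 0`) N = 2 reduction
#'   with `kon* = 2 kon^2/(kon + koff)`, `koff* = 2 koff^2/(kon + koff)` and
#'   shared initiation on `u1 + u2`;
#' * `"cobursting"`: the N = 1 bursty limit with shared geometric bursts on
#'   `u1 + u2` (`b = kinit/koff*`).
#'
#' @param kind coupling motif; `"driver_shared"` couples both genes to one
#'   gamma-OU transcription-rate process (`kappa`, `a`, `theta`, per-gene
#'   degradation `gamma1`, `gamma2`), correlating them through the driver
#'   trajectory.
#' @param params named list: for the state-coupled family `epsilon`, `kon`,
#'   `koff`, `kinit`, `gamma1`, `gamma2`; for mixtures `pi` (weights) and
#'   `components` (list of one-gene `gf_model`s per cell type, one per gene).
#' @return a `gf_model`, or for `"mixture"` a GF evaluator function.
#' @export
build_coupled_model <- function(kind = c("state_coupled", "cobursting_n2",
                                         "cobursting", "driver_shared",
                                         "mixture"), params) {
  kind <- match.arg(kind)
  p <- params
  if (kind == "driver_shared") {
    .pos(p$kappa, p$a, p$theta, p$gamma1, p$gamma2)
    rx <- list(rxn_degrade("K", p$kappa), rxn_jump("K", p$a, p$theta),
               rxn_drive("K", "x1", 1), rxn_drive("K", "x2", 1),
               rxn_degrade("x1", p$gamma1), rxn_degrade("x2", p$gamma2))
    return(assemble_operators(rx, discrete = c("x1", "x2"), continuous = "K",
                              params = p, family = "driver_shared"))
  }
  if (kind == "mixture") {
    w <- p$pi
    if (abs(sum(w) - 1) > 1e-10) stop("mixture weights must sum to 1")
    comps <- p$components  # list over cell types; each a list of per-gene models
    return(function(U, t = "stationary") {
      G <- 0 + 0i
      for (k in seq_along(w)) {
        Gk <- 1 + 0i
        for (j in seq_along(comps[[k]])) {
          mj <- comps[[k]][[j]]
          Gk <- Gk * gf_eval(mj, cbind(U[, j], matrix(0 + 0i, nrow(U), mj$m)), t = t)
        }
        G <- G + w[k] * Gk
      }
      G
    })
  }
  .pos(p$kon, p$koff, p$kinit, p$gamma1, p$gamma2)
  if (kind == "state_coupled") {
    .pos(p$epsilon)
    e <- 1 / p$epsilon
    kon <- p$kon; koff <- p$koff
    rx <- list(
      rxn_switch(1, 2, kon), rxn_switch(1, 3, kon),
      rxn_switch(2, 1, e * koff), rxn_switch(2, 4, e * kon),
      rxn_switch(3, 1, e * koff), rxn_switch(3, 4, e * kon),
      rxn_switch(4, 2, koff), rxn_switch(4, 3, koff),
      rxn_produce("x1", p$kinit, state = 2L),
      rxn_produce("x2", p$kinit, state = 3L),
      rxn_produce("x1", p$kinit, state = 4L),
      rxn_produce("x2", p$kinit, state = 4L),
      rxn_degrade("x1", p$gamma1), rxn_degrade("x2", p$gamma2))
    return(assemble_operators(rx, discrete = c("x1", "x2"), n_states = 4L,
                              params = p, family = "state_coupled"))
  }
  kap <- p$kon + p$koff
  kon_s <- 2 * p$kon^2 / kap
  koff_s <- 2 * p$koff^2 / kap
  if (kind == "cobursting_n2") {
    rx <- list(rxn_switch(1, 2, kon_s), rxn_switch(2, 1, koff_s),
               rxn_produce("x1", p$kinit, state = 2L),
               rxn_produce("x2", p$kinit, state = 2L),
               rxn_degrade("x1", p$gamma1), rxn_degrade("x2", p$gamma2))
    return(assemble_operators(rx, discrete = c("x1", "x2"), n_states = 2L,
                              params = c(p, list(kon_star = kon_s, koff_star = koff_s)),
                              family = "cobursting_n2"))
  }
  ## N = 1 co-bursting limit: shared geometric bursts on u1 + u2
  b <- p$kinit / koff_s
  rx <- list(rxn_burst(c("x1", "x2"), kon_s, b),
             rxn_degrade("x1", p$gamma1), rxn_degrade("x2", p$gamma2))
  assemble_operators(rx, discrete = c("x1", "x2"),
                     params = c(p, list(kon_star = kon_s, koff_star = koff_s, b = b)),
                     family = "cobursting")
}
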