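## Operator assembly: translate a list of elementary reactions into the
## unified (H, C, D, A) description of a gene-expression master equation.
##
## The state of a model is (s, x, y): s a categorical gene state (N values),
## x the copy numbers of n discrete species, y the values of m continuous
## species (transcription rates, high-abundance pools).  The generating
## function G_s(u, t) over the n+m spectral coordinates u obeys a first-order
## PDE whose characteristics satisfy
##     dU/ds = C U + diag(U) D U,
## while the N-vector of state-wise GFs obeys
##     dG/ds = -H^T G - G * A(U, T(s)),    T(s) = t - s.
## Everything the solvers need is assembled here.

#' Declare an elementary reaction
#'
#' Constructors for the reaction classes the generating-function method can
#' treat: gene-state switching, zero/first-order production (including
#' geometrically distributed bursts and compound-Poisson jumps of continuous
#' species), conversion, degradation/mean reversion, catalysis, drift and
#' square-root noise.  Higher-order (bimolecular, feedback) reactions are
#' outside the method of characteristics and are rejected by
#' [assemble_operators()].
#'
#' @param from,to gene-state indices (for `rxn_switch`) or species names
#'   (for `rxn_convert`).
#' @param rate nonnegative rate constant.
#' @param species species name the reaction acts on.
#' @param state gene state (index) in which a production channel is active;
#'   `NULL` means state 1 (or the only state).
#' @param freq burst/jump arrival frequency (per unit time); may be a
#'   function of process time for transient models.
#' @param mean_size mean of the geometric (discrete) or exponential
#'   (continuous) size distribution; may be a function of process time.
#' @param by,make catalyst and product species for `rxn_catalyze`
#'   (autocatalysis when identical).
#' @param driver continuous species whose value multiplies the production
#'   rate in `rxn_drive`.
#' @param target discrete species produced by `rxn_drive`.
#' @param sigma volatility of the square-root noise term.
#' @return an object of class `gf_reaction`.
#' @name reactions
NULL

.rxn <- function(kind, ...) structure(list(kind = kind, ...), class = "gf_reaction")

#' @rdname reactions
#' @export
rxn_switch <- function(from, to, rate) .rxn("switch", from = from, to = to, rate = rate)

#' @rdname reactions
#' @export
rxn_produce <- function(species, rate, state = NULL)
  .rxn("produce", species = species, rate = rate, state = state)

#' @rdname reactions
#' @export
rxn_burst <- function(species, freq, mean_size, state = NULL)
  .rxn("burst", species = species, freq = freq, mean_size = mean_size, state = state)

#' @rdname reactions
#' @export
rxn_convert <- function(from, to, rate) .rxn("convert", from = from, to = to, rate = rate)

#' @rdname reactions
#' @export
rxn_degrade <- function(species, rate) .rxn("degrade", species = species, rate = rate)

#' @rdname reactions
#' @export
rxn_catalyze <- function(by, make, rate) .rxn("catalyze", by = by, make = make, rate = rate)

#' @rdname reactions
#' @export
rxn_drift <- function(species, rate, state = NULL)
  .rxn("drift", species = species, rate = rate, state = state)

#' @rdname reactions
#' @export
rxn_jump <- function(species, freq, mean_size, state = NULL)
  .rxn("jump", species = species, freq = freq, mean_size = mean_size, state = state)

#' @rdname reactions
#' @export
rxn_sqrt_noise <- function(species, sigma) .rxn("sqrt_noise", species = species, sigma = sigma)

#' @rdname reactions
#' @export
rxn_drive <- function(driver, target, rate = 1)
  .rxn("drive", driver = driver, target = target, rate = rate)

.check_rate <- function(r, what) {
  if (is.function(r)) return(invisible(TRUE))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    stop(sprintf("invalid %s: must be a single nonnegative number", what), call. = FALSE)
  invisible(TRUE)
}

#' Assemble the unified operator system of a model
#'
#' Builds the gene-state transition matrix `H`, the linear downstream matrix
#' `C`, the quadratic (catalysis / square-root noise) matrix `D` and the
#' burst-and-drift operator `A` from a list of elementary reactions.  `C` and
#' `D` act on the spectral coordinates `u` ordered as (discrete species,
#' continuous species).
#'
#' @param reactions list of [reactions] objects.
#' @param discrete character vector naming the discrete species (may be
#'   empty).
#' @param continuous character vector naming the continuous species.
#' @param n_states number of gene states `N`.
#' @param params optional named list stashed on the model (used by family
#'   builders).
#' @param family optional family tag (used for closed forms and moments).
#' @param init_lgf optional function `f(U, model)` returning the log
#'   generating function of the initial molecular state evaluated at the
#'   spectral points `U` (a matrix with one column per species); default is
#'   all mass at zero (log-GF identically 0).
#' @param state_init optional initial gene-state occupancy vector; default is
#'   the stationary distribution of `H`.
#' @return an object of class `gf_model`.
#' @examples
#' m <- assemble_operators(
#'   list(rxn_produce("X", 3), rxn_degrade("X", 1)),
#'   discrete = "X")
#' m$C  # -gamma
#' @export
assemble_operators <- function(reactions, discrete = character(), continuous = character(),
                               n_states = 1L, params = list(), family = "custom",
                               init_lgf = NULL, state_init = NULL) {
  n <- length(discrete); m <- length(continuous)
  d <- n + m
  species <- c(discrete, continuous)
  if (anyDuplicated(species)) stop("species names must be unique")
  idx <- function(nm, kinds = species) {
    i <- match(nm, species)
    if (is.na(i)) stop(sprintf("unknown species '%s'", nm), call. = FALSE)
    i
  }
  is_cont <- function(i) i > n

  H <- matrix(0, n_states, n_states)
  C <- matrix(0, d, d, dimnames = list(species, species))
  D <- matrix(0, d, d, dimnames = list(species, species))
  src <- matrix("", d, d, dimnames = list(species, species))
  channels <- list()
  add_src <- function(i, j, tag) {
    src[i, j] <<- if (nzchar(src[i, j])) paste(src[i, j], tag, sep = "+") else tag
  }

  for (r in reactions) {
    if (!inherits(r, "gf_reaction"))
      stop("all elements of 'reactions' must be created with the rxn_* constructors")
    switch(r$kind,
      "switch" = {
        .check_rate(r$rate, "switching rate")
        if (r$from > n_states || r$to > n_states) stop("gene-state index out of range")
        H[r$from, r$to] <- H[r$from, r$to] + r$rate
      },
      "convert" = {
        .check_rate(r$rate, "conversion rate")
        i <- idx(r$from); j <- idx(r$to)
        if (is_cont(i) || is_cont(j)) stop("rxn_convert applies to discrete species")
        C[i, i] <- C[i, i] - r$rate
        C[i, j] <- C[i, j] + r$rate
        add_src(i, i, "Cdd"); add_src(i, j, "Cdd")
      },
      "degrade" = {
        .check_rate(r$rate, "degradation rate")
        i <- idx(r$species)
        C[i, i] <- C[i, i] - r$rate
        add_src(i, i, if (is_cont(i)) "Ccc" else "Cdd")
      },
      "catalyze" = {
        .check_rate(r$rate, "catalysis rate")
        i <- idx(r$by); j <- idx(r$make)
        if (is_cont(i)) stop("the catalyst of rxn_catalyze must be discrete")
        C[i, j] <- C[i, j] + r$rate
        D[i, j] <- D[i, j] + r$rate
        tag <- if (is_cont(j)) "Cdc" else "Qd"
        add_src(i, j, tag)
      },
      "drive" = {
        .check_rate(r$rate, "driving rate")
        i <- idx(r$driver); j <- idx(r$target)
        if (!is_cont(i) || is_cont(j)) stop("rxn_drive couples a continuous driver to a discrete target")
        C[i, j] <- C[i, j] + r$rate
        add_src(i, j, "Ccd")
      },
      "sqrt_noise" = {
        .check_rate(r$sigma, "volatility")
        i <- idx(r$species)
        if (!is_cont(i)) stop("square-root noise applies to continuous species")
        D[i, i] <- D[i, i] + r$sigma^2 / 2
        add_src(i, i, "Qc")
      },
      "produce" = {
        .check_rate(r$rate, "production rate")
        i <- idx(r$species)
        w <- numeric(d); w[i] <- 1
        channels[[length(channels) + 1L]] <-
          list(state = r$state %||% 1L, rate = r$rate, kind = "delta", w = w)
      },
      "drift" = {
        .check_rate(r$rate, "drift rate")
        i <- idx(r$species)
        if (!is_cont(i)) stop("rxn_drift applies to continuous species")
        w <- numeric(d); w[i] <- 1
        channels[[length(channels) + 1L]] <-
          list(state = r$state %||% 1L, rate = r$rate, kind = "delta", w = w)
      },
      "burst" = {
        .check_rate(r$freq, "burst frequency")
        if (!is.function(r$mean_size)) .check_rate(r$mean_size, "burst size")
        i <- vapply(r$species, idx, 1L)
        w <- numeric(d); w[i] <- 1
        channels[[length(channels) + 1L]] <-
          list(state = r$state %||% 1L, rate = r$freq, kind = "geometric",
               w = w, size = r$mean_size)
      },
      "jump" = {
        .check_rate(r$freq, "jump frequency")
        .check_rate(r$mean_size, "jump mean")
        i <- idx(r$species)
        if (!is_cont(i)) stop("rxn_jump applies to continuous species")
        w <- numeric(d); w[i] <- 1
        channels[[length(channels) + 1L]] <-
          list(state = r$state %||% 1L, rate = r$freq, kind = "geometric",
               w = w, size = r$mean_size)
      },
      stop(sprintf(paste0("unsupported reaction kind '%s': only zero- and first-order ",
                          "reactions (no feedback or bimolecular steps) can be treated ",
                          "by the method of characteristics"), r$kind), call. = FALSE)
    )
  }
  diag(H) <- 0
  diag(H) <- -rowSums(H)

  model <- structure(list(
    N = n_states, n = n, m = m,
    species = species, discrete = discrete, continuous = continuous,
    H = H, C = C, D = D, block_sources = src,
    channels = channels,
    init_lgf = init_lgf,
    state_init = state_init,
    params = params, family = family
  ), class = "gf_model")
  validate_gf_model(model)
  model
}

validate_gf_model <- function(model) {
  H <- model$H
  off <- H; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal gene-state rates must be nonnegative")
  if (any(abs(rowSums(H)) > 1e-10)) stop("gene-state transition matrix rows must sum to zero")
  for (ch in model$channels) {
    if (length(ch$w) != model$n + model$m) stop("channel dimensionality mismatch")
    if (ch$state > model$N) stop("channel gene state out of range")
  }
  invisible(model)
}

## Burst/drift operator A(U, T): npts x N complex matrix.  U is an
## npts x (n+m) complex matrix of characteristic values; tproc the process
## time at which time-dependent channel parameters are evaluated.
A_eval <- function(model, U, tproc = NULL) {
  npts <- nrow(U)
  A <- matrix(0 + 0i, npts, model$N)
  for (ch in model$channels) {
    v <- as.vector(U %*% ch$w)
    rate <- if (is.function(ch$rate)) ch$rate(tproc) else ch$rate
    contrib <- switch(ch$kind,
      delta = v,
      geometric = {
        b <- if (is.function(ch$size)) ch$size(tproc) else ch$size
        bv <- b * v
        bv / (1 - bv)
      },
      stop("unknown channel kind"))
    A[, ch$state] <- A[, ch$state] + rate * contrib
  }
  A
}

## Stationary gene-state occupancy of H (left null vector of H, i.e. the
## stationary law of the chain with generator H acting row-wise).
state_occupancy <- function(H) {
  N <- nrow(H)
  if (N == 1L) return(1)
  M <- rbind(t(H), rep(1, N))
  qr.solve(M, c(numeric(N), 1))
}

model_init_gf <- function(model, Ut) {
  ## G0 evaluated at the characteristic endpoints: npts x N matrix
  npts <- nrow(Ut)
  pi0 <- model$state_init %||% state_occupancy(model$H)
  lg <- if (is.null(model$init_lgf)) matrix(0 + 0i, npts, model$N)
        else {
          v <- model$init_lgf(Ut, model)
          if (is.null(dim(v))) matrix(v, npts, model$N) else v
        }
  exp(lg) * matrix(rep(pi0, each = npts), npts, model$N)
}

## Smallest characteristic rate of the model, used to size the quadrature
## horizon for stationary solves.
min_rate <- function(model) {
  r <- c(abs(model$C[model$C != 0]), abs(model$D[model$D != 0]))
  off <- model$H; diag(off) <- 0
  r <- c(r, off[off != 0])
  for (ch in model$channels) if (!is.function(ch$rate)) r <- c(r, ch$rate)
  r <- r[r > 0]
  if (!length(r)) 1 else min(r)
}

#' @export
#' @method print gf_model
print.gf_model <- function(x, ...) {
  cat(sprintf("<gf_model: %s>\n", x$family))
  cat(sprintf("  gene states N = %d; discrete species n = %d (%s); continuous m = %d (%s)\n",
              x$N, x$n, paste(x$discrete, collapse = ","),
              x$m, paste(x$continuous, collapse = ",")))
  cat(sprintf("  %d production/drift channel(s); D %s zero\n",
              length(x$channels), if (all(x$D == 0)) "is" else "is not"))
  if (length(x$params)) {
    p <- vapply(x$params, function(z) if (is.numeric(z) && length(z) == 1) format(z, digits = 5) else "<...>", "")
    cat("  params:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
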