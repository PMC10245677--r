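## Method-of-characteristics machinery.
##
## The downstream ODE dU/ds = C U + diag(U) D U is solved either in closed
## form (eigendecomposition, when D = 0) or by an adaptive embedded
## Runge-Kutta pair vectorized over all spectral start points at once
## (complex arithmetic; Dormand-Prince 5(4), rtol 1e-8 / atol 1e-10 by
## default).  The upstream state-weight ODE is integrated backwards along
## the same characteristics.

.DP <- list(
  c = c(0, 1/5, 3/10, 4/5, 8/9, 1, 1),
  a = list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)),
  b5 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0),
  b4 = c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40))

## Integrate dY/ds = f(s, Y) for a complex matrix state Y from s0 to s1
## (s1 > s0), optionally storing the solution at the sorted points out_s.
rk_complex <- function(f, Y0, s0, s1, rtol = 1e-8, atol = 1e-10, out_s = NULL,
                       max_steps = 200000L) {
  Y <- Y0
  s <- s0
  span <- s1 - s0
  if (span <= 0) {
    if (span == 0) return(list(Y = Y, out = if (is.null(out_s)) NULL else rep(list(Y), length(out_s))))
    stop("rk_complex integrates forward only")
  }
  out <- NULL
  if (!is.null(out_s)) {
    out <- vector("list", length(out_s))
    next_out <- 1L
  }
  h <- span / 100
  k <- vector("list", 7)
  k[[1]] <- f(s, Y)
  nsteps <- 0L
  while (s < s1 - 1e-14 * abs(span)) {
    nsteps <- nsteps + 1L
    if (nsteps > max_steps) stop("characteristic integrator exceeded the step budget")
    h <- min(h, s1 - s)
    if (!is.null(out) && next_out <= length(out_s)) {
      gap <- out_s[next_out] - s
      if (gap > 1e-13 * max(abs(span), 1)) h <- min(h, gap)
    }
    for (i in 2:6) {
      acc <- .DP$a[[i - 1]][1] * k[[1]]
      if (i > 2) for (j in 2:(i - 1)) acc <- acc + .DP$a[[i - 1]][j] * k[[j]]
      k[[i]] <- f(s + .DP$c[i] * h, Y + h * acc)
    }
    acc5 <- .DP$b5[1] * k[[1]]
    for (j in 2:6) if (.DP$b5[j] != 0) acc5 <- acc5 + .DP$b5[j] * k[[j]]
    Y5 <- Y + h * acc5
    k[[7]] <- f(s + h, Y5)
    acc4 <- .DP$b4[1] * k[[1]]
    for (j in 2:7) if (.DP$b4[j] != 0) acc4 <- acc4 + .DP$b4[j] * k[[j]]
    Y4 <- Y + h * acc4
    sc <- atol + rtol * pmax(Mod(Y), Mod(Y5))
    err <- max(Mod(Y5 - Y4) / sc)
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      s <- s + h
      Y <- Y5
      k[[1]] <- k[[7]]
      ## output points are never overstepped (h is capped above), so any
      ## pending point within rounding of s has just been reached exactly
      if (!is.null(out)) {
        while (next_out <= length(out_s) &&
               out_s[next_out] <= s + 1e-12 * max(abs(span), 1)) {
          out[[next_out]] <- Y
          next_out <- next_out + 1L
        }
      }
    }
    fac <- 0.9 * if (err > 0) err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  if (!is.null(out)) {
    for (i in seq_along(out)) if (is.null(out[[i]])) out[[i]] <- Y
  }
  list(Y = Y, out = out)
}

## Closed-form characteristic propagator for D = 0 systems:
## U(s) = V exp(Lambda s) V^{-1} u, with a numeric fallback when C is not
## (numerically) diagonalizable.
char_propagator <- function(model, tol = 1e-8) {
  C <- model$C
  d <- nrow(C)
  if (d == 0L) return(function(U0, s) U0)
  if (any(model$D != 0)) return(NULL)
  eg <- eigen(C)
  lam <- eg$values
  V <- eg$vectors
  ## repeated eigenvalues or an ill-conditioned eigenbasis: fall back to
  ## numeric integration (generalized-eigenvector regime)
  if (d > 1) {
    gaps <- outer(lam, lam, function(a, b) Mod(a - b))
    diag(gaps) <- Inf
    if (min(gaps) < tol * max(1, max(Mod(lam)))) return(NULL)
  }
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || max(Mod(V %*% Vi - diag(d))) > 1e-8) return(NULL)
  function(U0, s) {
    ## U0: npts x d complex; returns npts x d at a single time s
    E <- exp(lam * s)
    P <- V %*% (E * Vi)          # V diag(e^{lam s}) V^{-1}
    U0 %*% t(P)
  }
}

char_rhs <- function(model) {
  Ct <- t(model$C)
  Dt <- t(model$D)
  has_D <- any(model$D != 0)
  function(s, U) {
    dU <- U %*% Ct
    if (has_D) dU <- dU + U * (U %*% Dt)
    dU
  }
}

## Characteristics evaluated at requested path times (npts x d x length(s)).
char_at <- function(model, U0, s_vec, rtol = 1e-8, atol = 1e-10) {
  d <- model$n + model$m
  npts <- nrow(U0)
  prop <- char_propagator(model)
  out <- array(0 + 0i, c(npts, max(d, 1L), length(s_vec)))
  if (d == 0L) return(out)
  if (!is.null(prop)) {
    for (i in seq_along(s_vec)) out[, , i] <- prop(U0, s_vec[i])
    return(out)
  }
  ord <- order(s_vec)
  sv <- s_vec[ord]
  pos <- sv > 0
  res <- vector("list", length(sv))
  if (any(!pos)) for (i in which(!pos)) res[[i]] <- U0
  if (any(pos)) {
    sol <- rk_complex(char_rhs(model), U0, 0, max(sv), rtol = rtol, atol = atol,
                      out_s = sv[pos])
    res[which(pos)] <- sol$out
  }
  for (i in seq_along(sv)) out[, , ord[i]] <- res[[i]]
  out
}

#' Solve the downstream characteristic ODE
#'
#' Integrates `dU/ds = C U + diag(U) D U` with `U(0) = u` over `[0, t]`.
#' When `D = 0` and `C` is diagonalizable with distinct eigenvalues the
#' closed-form eigendecomposition solution is used; otherwise (repeated
#' eigenvalues, quadratic terms) the system is integrated numerically with
#' an adaptive Runge-Kutta pair and a message notes the fallback.
#'
#' @param model a [gf_model][assemble_operators] (its `C` and `D` are used).
#' @param u complex spectral start point(s): a vector of length `n + m` or a
#'   matrix with one row per start point.
#' @param t duration (`>= 0`).
#' @param nodes number of quadrature nodes at which the path is stored
#'   (`>= 2`).
#' @return an object of class `char_path` with elements `s` (nodes in
#'   `[0, t]`), `U` (array `npts x (n+m) x nodes`) and `t`.
#' @export
solve_characteristics <- function(model, u, t, nodes = 129L) {
  if (t < 0) stop("t must be nonnegative")
  if (nodes < 2) stop("at least 2 nodes are required")
  U0 <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  if (ncol(U0) != model$n + model$m) stop("spectral dimensionality mismatch")
  storage.mode(U0) <- "complex"
  s_vec <- seq(0, t, length.out = nodes)
  if (is.null(char_propagator(model)) && all(model$D == 0))
    message("C is not cleanly diagonalizable; characteristics integrated numerically")
  U <- char_at(model, U0, s_vec)
  structure(list(s = s_vec, U = U, t = t, u = U0), class = "char_path")
}

## ---- upstream integration -------------------------------------------------

## Quadrature panels on [0, horizon]: geometrically refined toward 0 so the
## exponential decay of U is resolved, with Gauss-Legendre nodes per panel.
gl_panels <- function(horizon, minrate = 1, n_per_panel = 16L) {
  if (horizon <= 0) return(list(x = numeric(), w = numeric()))
  K <- max(8L, min(60L, ceiling(log2(horizon * max(minrate, 1e-12))) + 10L))
  edges <- c(0, horizon * 2^(-(K:1)), horizon)
  edges <- unique(pmin(edges, horizon))
  xs <- ws <- NULL
  for (i in seq_len(length(edges) - 1L)) {
    gl <- pracma::gaussLegendre(n_per_panel, edges[i], edges[i + 1L])
    xs <- c(xs, gl$x); ws <- c(ws, gl$w)
  }
  list(x = xs, w = ws)
}

stationary_horizon <- function(model, decades = 40) decades / min_rate(model)

#' Evaluate a model's generating function at spectral points
#'
#' Solves the characteristic system and integrates the upstream ODE (or the
#' single quadrature, for one-state models) to produce the generating
#' function at the supplied shifted spectral points.  Continuous species'
#' coordinates are included in `U0` (pass zeros to marginalize them).
#'
#' @param model a [gf_model][assemble_operators].
#' @param U0 complex matrix of spectral points (`npts x (n + m)`).
#' @param t duration, or `"stationary"` (integrates over a horizon of 40
#'   relaxation times of the slowest rate).
#' @param marginal sum the per-state GFs over the gene state
#'   ([marginalize_gene_state()])?
#' @param rtol,atol adaptive Runge-Kutta tolerances.
#' @param n_per_panel Gauss-Legendre nodes per quadrature panel.
#' @return complex vector of GF values (or an `npts x N` matrix when
#'   `marginal = FALSE`).
#' @export
gf_eval <- function(model, U0, t = "stationary", marginal = TRUE,
                    rtol = 1e-8, atol = 1e-10, n_per_panel = 16L) {
  stationary <- identical(t, "stationary")
  tt <- if (stationary) stationary_horizon(model) else t
  npts <- nrow(U0)
  d <- model$n + model$m
  storage.mode(U0) <- "complex"

  if (model$N == 1L) {
    ## single quadrature: phi(t) = phi0(U(t)) + int_0^t A(U(s), t - s) ds
    q <- gl_panels(tt, min_rate(model), n_per_panel)
    sv <- c(q$x, tt)
    Upath <- char_at(model, U0, sv, rtol, atol)
    phi <- numeric(npts) + 0i
    for (i in seq_along(q$x)) {
      phi <- phi + q$w[i] * A_eval(model, matrix(Upath[, , i], npts, d),
                                   tproc = if (stationary) NULL else tt - q$x[i])[, 1]
    }
    Ut <- matrix(Upath[, , length(sv)], npts, d)
    G0 <- model_init_gf(model, Ut)
    G <- G0[, 1] * exp(phi)
    return(if (marginal) G else matrix(G, npts, 1))
  }

  ## N > 1: propagate G backwards along the characteristics.
  prop <- char_propagator(model)
  Hfun <- if (is.function(model$H)) model$H else NULL
  Hconst <- if (is.null(Hfun)) model$H else NULL
  if (!is.null(prop)) {
    Ut <- prop(U0, tt)
    G0 <- model_init_gf(model, Ut)
    rhs <- function(tau, G) {
      U <- prop(U0, tt - tau)
      H <- if (is.null(Hfun)) Hconst else Hfun(tau)
      G %*% H + G * A_eval(model, U, tproc = if (stationary) NULL else tau)
    }
    G <- rk_complex(rhs, G0, 0, tt, rtol, atol)$Y
  } else {
    ## joint backward system (U, G); U(tau = 0) = U(t) from a forward pass
    Ut <- char_at(model, U0, tt, rtol, atol)[, , 1]
    Ut <- matrix(Ut, npts, d)
    G0 <- model_init_gf(model, Ut)
    Ct <- t(model$C); Dt <- t(model$D)
    has_D <- any(model$D != 0)
    rhs <- function(tau, Y) {
      U <- Y[, seq_len(d), drop = FALSE]
      G <- Y[, d + seq_len(model$N), drop = FALSE]
      dU <- U %*% Ct
      if (has_D) dU <- dU + U * (U %*% Dt)
      H <- if (is.null(Hfun)) Hconst else Hfun(tau)
      dG <- G %*% H + G * A_eval(model, U, tproc = if (stationary) NULL else tau)
      cbind(-dU, dG)
    }
    Y <- rk_complex(rhs, cbind(Ut, G0), 0, tt, rtol, atol)$Y
    G <- Y[, d + seq_len(model$N), drop = FALSE]
  }
  if (marginal) rowSums(G) else G
}

#' Integrate the upstream generating-function ODE along a characteristic path
#'
#' For single-state models (`N = 1`) this reduces to one quadrature of the
#' burst/drift operator over the stored path; for `N > 1` the state-weight
#' ODE `dG/ds = -H^T G - G * A(U(s), T(s))` is integrated with initial
#' condition `G0(U(t))`, and time-dependent rates are evaluated at the
#' process time `T(s) = t - s`.
#'
#' @param model a [gf_model][assemble_operators].
#' @param path a `char_path` from [solve_characteristics()] computed for the
#'   same model and duration.
#' @param marginal sum the per-state GFs over the gene state?
#' @return complex GF value(s): a vector (marginalized) or an
#'   `npts x N` matrix of per-state values.
#' @export
integrate_upstream <- function(model, path, marginal = TRUE) {
  if (!inherits(path, "char_path")) stop("'path' must come from solve_characteristics()")
  d <- model$n + model$m
  if (dim(path$U)[2] != max(d, 1L))
    stop("mismatched durations or dimensions between model and path")
  gf_eval(model, path$u, t = path$t, marginal = marginal)
}
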