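## Synthetic-data generation: exact SSA of the transient bursty model,
## rejection sampling of transcriptional parameters, and droplet datasets
## mixing overdispersed "cell" counts with independent-Poisson empties.

#' Simulate the transient bursty model by exact SSA
#'
#' Gillespie simulation of bursty transcription with a time-dependent
#' geometric burst-size mean (piecewise constant, so event rates are
#' constant between events and the algorithm is exact), splicing and
#' degradation; each requested age is observed on an independent trajectory
#' started from the bivariate-Poisson initial condition.
#'
#' @param params a [transient_params()].
#' @param ages observation times (one stored state per age per rep).
#' @param seed optional integer seed.
#' @param reps trajectories per age.
#' @return integer matrix with columns `xN`, `xM` (rows ordered by age,
#'   then rep).
#' @export
ssa_transient <- function(params, ages, seed = NULL, reps = 1L) {
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_ssa_transient(c(params$b, params$alpha, params$beta, params$gamma),
                           params$tau[1], params$tau[2], as.numeric(ages),
                           as.integer(reps))
  colnames(out) <- c("xN", "xM")
  out
}

#' Simulate the (bursty) autocatalytic network by exact SSA
#' @param alpha,q,gamma,b model rates ([autocatalytic_model()]); `b = NULL`
#'   means single-molecule production events.
#' @param t_end simulation horizon (start state 0).
#' @param reps number of trajectories.
#' @param seed optional integer seed.
#' @return integer vector of copy numbers at `t_end`.
#' @export
ssa_autocatalytic <- function(alpha, q, gamma, b = NULL, t_end, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_ssa_autocat(alpha, q, gamma, b %||% -1, t_end, as.integer(reps))
}

#' Rejection-sample transient-model parameters
#'
#' Draws `log10 b_i ~ N(0.8, 1)` and the other log10 parameters from
#' `N(0, 1)`, clips all to `[10^-1.4, 10^1.4]`, and accepts the proposal iff,
#' at the largest stage burst size, both `muN + 4*sigmaN` and
#' `muM + 4*sigmaM` are below 25 (bursty-model moment formulas), which keeps
#' the PMF evaluation grid near 25 x 25.
#'
#' @param seed optional integer seed.
#' @param tau stage-change times of the returned parameter set.
#' @param max_tries retry budget before failing.
#' @return a [transient_params()].
#' @export
draw_transient_params <- function(seed = NULL, tau = c(1, 3), max_tries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  clip <- function(z) pmin(pmax(z, -1.4), 1.4)
  for (i in seq_len(max_tries)) {
    b <- 10^clip(rnorm(3, mean = 0.8, sd = 1))
    other <- 10^clip(rnorm(3, mean = 0, sd = 1))
    alpha <- other[1]; beta <- other[2]; gamma <- other[3]
    bmax <- max(b)
    muN <- alpha * bmax / beta
    sdN <- sqrt(muN * (1 + bmax))
    muM <- alpha * bmax / gamma
    sdM <- sqrt(muM * (1 + bmax * beta / (beta + gamma)))
    if (muN + 4 * sdN < 25 && muM + 4 * sdM < 25)
      return(transient_params(b, tau, alpha, beta, gamma))
  }
  stop("rejection sampling failed within the retry budget")
}

#' Apply molecule-level technical noise to counts
#'
#' Realizes the library-construction transforms at the sample level:
#' sequestering noise thins each molecule independently (binomial),
#' non-sequestering noise replicates each molecule a Poisson number of
#' times.
#'
#' @param counts integer matrix (observations x species).
#' @param noise a [library_noise()] with one entry per column.
#' @param seed optional integer seed.
#' @return noised count matrix.
#' @export
apply_count_noise <- function(counts, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.matrix(counts)
  if (ncol(counts) != noise$n) stop("noise dimensionality mismatch")
  out <- counts
  for (i in seq_len(noise$n)) {
    out[, i] <- if (noise$mode[i] == "sequestering")
      rbinom(nrow(counts), counts[, i], noise$p[i])
    else
      rpois(nrow(counts), noise$lambda[i] * counts[, i])
  }
  out
}

#' Simulate a synthetic droplet dataset
#'
#' Generates per-droplet nascent/mature UMI counts for a panel of genes:
#' cell-containing droplets draw from each gene's stationary model PMF
#' (bursty two-species by default), empty droplets draw independent Poisson
#' background with per-gene means `c * mu_i * p_i`, and an optional
#' aggregate-contamination channel adds compound-Poisson bursts (whole
#' mitochondria / erythrocytes entering droplets and lysing) to a flagged
#' gene subset in the empties.
#'
#' @param genes list of per-gene parameter lists `(alpha, b, beta, gamma)`,
#'   or an integer number of genes to draw at random.
#' @param n_cells,n_empty droplet counts per class.
#' @param c_bg background pool-size constant.
#' @param capture optional per-species capture probabilities `(pN, pM)`
#'   applied as Bernoulli thinning to all droplets.
#' @param aggregate optional list `(genes, rate, size)`: flagged gene
#'   indices, per-droplet aggregate arrival rate, and mean geometric number
#'   of mature molecules released per aggregate.
#' @param seed integer seed (all randomness derives from it).
#' @return a list of class `droplet_dataset`: `nascent` and `mature` count
#'   matrices (droplets x genes), `labels` (`"cell"`/`"empty"`), and
#'   `meta` (generator truth).
#' @export
simulate_droplets <- function(genes, n_cells = 2000L, n_empty = 4000L,
                              c_bg = 1e-2, capture = c(1, 1),
                              aggregate = NULL, seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- replicate(genes, list(alpha = 10^runif(1, -0.5, 0.5),
                                   b = 10^runif(1, 0, 0.8),
                                   beta = 10^runif(1, -0.3, 0.3),
                                   gamma = 10^runif(1, -0.3, 0.3)),
                       simplify = FALSE)
  }
  ngene <- length(genes)
  nasc <- matrix(0L, n_cells + n_empty, ngene)
  mat <- matrix(0L, n_cells + n_empty, ngene)
  muN <- muM <- numeric(ngene)
  set.seed(derive_seed(seed, 2L))
  for (j in seq_len(ngene)) {
    g <- genes[[j]]
    muN[j] <- g$alpha * g$b / g$beta
    muM[j] <- g$alpha * g$b / g$gamma
    ## cells: marginals of the stationary bursty law; nascent and mature are
    ## drawn from the gene's joint PMF
    mdl <- bursty_model(g$alpha, g$b, g$beta, g$gamma)
    pmf <- gf_to_pmf(mdl)
    xs <- sample_pmf(pmf, n_cells)
    nasc[seq_len(n_cells), j] <- xs[, 1]
    mat[seq_len(n_cells), j] <- xs[, 2]
    ## empties: independent Poisson with pseudobulk means
    nasc[n_cells + seq_len(n_empty), j] <- rpois(n_empty, c_bg * muN[j])
    mat[n_cells + seq_len(n_empty), j] <- rpois(n_empty, c_bg * muM[j])
  }
  if (!is.null(aggregate)) {
    set.seed(derive_seed(seed, 3L))
    for (j in aggregate$genes) {
      k <- rpois(n_empty, aggregate$rate)
      extra <- vapply(k, function(ki) if (ki == 0) 0L else
        sum(rgeom(ki, 1 / (1 + aggregate$size))), 0L)
      mat[n_cells + seq_len(n_empty), j] <- mat[n_cells + seq_len(n_empty), j] + extra
    }
  }
  if (any(capture < 1)) {
    set.seed(derive_seed(seed, 4L))
    nasc[] <- rbinom(length(nasc), nasc, capture[1])
    mat[] <- rbinom(length(mat), mat, capture[2])
  }
  labels <- rep(c("cell", "empty"), c(n_cells, n_empty))
  colnames(nasc) <- colnames(mat) <- sprintf("gene%03d", seq_len(ngene))
  rownames(nasc) <- rownames(mat) <- sprintf("bc%05d", seq_len(n_cells + n_empty))
  structure(list(nascent = nasc, mature = mat, labels = labels,
                 meta = list(c_bg = c_bg, muN = muN, muM = muM,
                             capture = capture, genes = genes,
                             aggregate = aggregate, seed = seed)),
            class = "droplet_dataset")
}

#' Write a droplet dataset as MatrixMarket + TSV files
#'
#' One sparse MTX per species (genes x droplets, the conventional
#' orientation), `barcodes.tsv`, `genes.tsv`, a label TSV and a JSON
#' metadata file recording the generator truth and seed.
#'
#' @param x a `droplet_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_droplet_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(x$nascent), sparse = TRUE),
                  file.path(dir, "nascent.mtx"))
  Matrix::writeMM(Matrix::Matrix(t(x$mature), sparse = TRUE),
                  file.path(dir, "mature.mtx"))
  writeLines(rownames(x$nascent), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$nascent), file.path(dir, "genes.tsv"))
  writeLines(x$labels, file.path(dir, "labels.tsv"))
  meta <- x$meta
  meta$genes <- NULL
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
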