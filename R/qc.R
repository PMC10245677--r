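## Empty-droplet diagnostics.
##
## Under the pseudobulk background model, empty-droplet counts are
## independent Poisson per gene with means proportional to the population
## means.  That yields four testable predictions on raw counts: an identity
## mean-variance relationship, near-zero nascent/mature correlation within
## genes, near-zero correlations between genes, and empty-vs-cell mean
## proportionality; total UMI counts should then have Fano factor ~ 1.
## Genes violating Poisson dispersion (sigma^2 > 2*mu, e.g. mitochondrial or
## erythrocyte aggregates that lyse inside droplets) are flagged.

#' Load droplet count matrices written as MatrixMarket + TSV
#'
#' Reads the `nascent.mtx`/`mature.mtx` pair (genes x droplets), barcode and
#' gene TSVs and the empty/non-empty label vector produced by
#' [write_droplet_counts()] (or any pipeline using the same dialect).
#'
#' @param dir directory holding `nascent.mtx`, `mature.mtx`,
#'   `barcodes.tsv`, `genes.tsv` and `labels.tsv`.
#' @return list with dense `nascent` and `mature` matrices
#'   (droplets x genes) and the `labels` vector.
#' @export
load_counts <- function(dir) {
  need <- c("nascent.mtx", "mature.mtx", "barcodes.tsv", "genes.tsv", "labels.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  nasc <- t(as.matrix(Matrix::readMM(paths[1])))
  mat <- t(as.matrix(Matrix::readMM(paths[2])))
  storage.mode(nasc) <- storage.mode(mat) <- "integer"
  barcodes <- readLines(paths[3])
  genes <- readLines(paths[4])
  labels <- readLines(paths[5])
  if (nrow(nasc) != length(barcodes) || ncol(nasc) != length(genes) ||
      !all(dim(nasc) == dim(mat)))
    stop("count matrix dimensions do not match the barcode/gene files")
  if (length(labels) != length(barcodes))
    stop("label vector length does not match the barcodes")
  dimnames(nasc) <- dimnames(mat) <- list(barcodes, genes)
  list(nascent = nasc, mature = mat, labels = labels)
}

#' Per-gene mean and variance table
#'
#' @param m count matrix (droplets x genes).
#' @return data.frame with per-gene `mean` and `var`; the attribute
#'   `loglog_fit` holds the slope/intercept of the log-log variance~mean
#'   regression over genes where both are nonzero.
#' @export
mean_variance_table <- function(m) {
  if (!nrow(m)) stop("empty count matrix")
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  out <- data.frame(gene = colnames(m) %||% seq_along(mu), mean = mu, var = v)
  ok <- mu > 0 & v > 0
  fit <- if (sum(ok) >= 2) {
    cf <- coef(lm(log10(v[ok]) ~ log10(mu[ok])))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  } else c(intercept = NA_real_, slope = NA_real_)
  attr(out, "loglog_fit") <- fit
  out
}

#' Intra- and inter-gene correlation screens
#'
#' Pearson correlations on raw counts: within each gene between its nascent
#' and mature counts, and between genes within each species (restricted to
#' expressed genes, i.e. nonzero total count).  Undefined correlations
#' (zero-variance genes) are omitted.
#'
#' @param nascent,mature count matrices (droplets x genes).
#' @return list with `intra` (per-gene rho), `inter_nascent` and
#'   `inter_mature` (vectors over gene pairs).
#' @export
correlation_screens <- function(nascent, mature) {
  if (nrow(nascent) < 2) return(list(intra = numeric(), inter_nascent = numeric(),
                                     inter_mature = numeric()))
  intra <- vapply(seq_len(ncol(nascent)), function(j) {
    if (var(nascent[, j]) == 0 || var(mature[, j]) == 0) return(NA_real_)
    cor(nascent[, j], mature[, j])
  }, 1)
  intra <- intra[!is.na(intra)]
  pair_cors <- function(m) {
    m <- m[, colSums(m) > 0, drop = FALSE]
    m <- m[, apply(m, 2, var) > 0, drop = FALSE]
    if (ncol(m) < 2) return(numeric())
    cc <- cor(m)
    cc[upper.tri(cc)]
  }
  list(intra = intra, inter_nascent = pair_cors(nascent),
       inter_mature = pair_cors(mature))
}

#' Flag overdispersed genes
#'
#' Flags genes with `var > 2 * mean` (the Poisson-violation rule used to
#' identify aggregate contamination in empty droplets).
#'
#' @param m count matrix (droplets x genes).
#' @return integer vector of flagged gene indices.
#' @export
overdispersion_screen <- function(m) {
  if (!nrow(m)) return(integer())
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  which(v > 2 * mu & mu > 0)
}

#' Fano factor of per-droplet total counts
#'
#' @param m count matrix (droplets x genes).
#' @param exclude optional gene indices to drop before totalling.
#' @return variance/mean of the per-droplet totals (`NA` when undefined:
#'   fewer than two droplets or zero mean).
#' @export
total_count_fano <- function(m, exclude = NULL) {
  if (length(exclude)) m <- m[, -exclude, drop = FALSE]
  if (nrow(m) < 2) return(NA_real_)
  tot <- rowSums(m)
  mu <- mean(tot)
  if (mu == 0) return(NA_real_)
  var(tot) / mu
}

#' Empty-droplet quality-control report
#'
#' Runs the full diagnostic battery on labelled nascent/mature matrices:
#' per-gene mean-variance tables and log-log fits for empty and non-empty
#' droplets, intra-/inter-gene correlation screens, the overdispersed-gene
#' flag list (mature counts in empties), total-count Fano factors with and
#' without the flagged genes, and the empty-vs-cell log-mean regression.
#'
#' @param nascent,mature count matrices (droplets x genes).
#' @param labels character vector (`"cell"` / `"empty"`) per droplet.
#' @return list of class `qc_report`.
#' @export
qc_report <- function(nascent, mature, labels) {
  if (length(labels) != nrow(nascent)) stop("label vector length mismatch")
  emp <- labels == "empty"
  rep_ <- list(
    mv_empty_mature = mean_variance_table(mature[emp, , drop = FALSE]),
    mv_cell_mature = mean_variance_table(mature[!emp, , drop = FALSE]),
    correlations_empty = correlation_screens(nascent[emp, , drop = FALSE],
                                             mature[emp, , drop = FALSE]),
    flagged = overdispersion_screen(mature[emp, , drop = FALSE]))
  rep_$fano_all <- total_count_fano(mature[emp, , drop = FALSE])
  rep_$fano_filtered <- total_count_fano(mature[emp, , drop = FALSE], rep_$flagged)
  mu_e <- colMeans(mature[emp, , drop = FALSE])
  mu_c <- colMeans(mature[!emp, , drop = FALSE])
  ok <- mu_e > 0 & mu_c > 0
  rep_$mean_regression <- if (sum(ok) >= 2) {
    cf <- coef(lm(log10(mu_e[ok]) ~ log10(mu_c[ok])))
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         rho = cor(log10(mu_e[ok]), log10(mu_c[ok])))
  } else list(intercept = NA_real_, slope = NA_real_, rho = NA_real_)
  structure(rep_, class = "qc_report")
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("<empty-droplet QC report>\n")
  f <- attr(x$mv_empty_mature, "loglog_fit")
  cat(sprintf("  empty mature var~mean log-log slope %.3f, intercept %.3f\n",
              f["slope"], f["intercept"]))
  cat(sprintf("  empty intra-gene mean |rho| = %.4f (%d genes)\n",
              mean(abs(x$correlations_empty$intra)),
              length(x$correlations_empty$intra)))
  cat(sprintf("  flagged overdispersed genes: %d\n", length(x$flagged)))
  cat(sprintf("  total mature-count Fano: %.3f (all) / %.3f (flags removed)\n",
              x$fano_all, x$fano_filtered))
  cat(sprintf("  empty-vs-cell log-mean slope %.3f (rho %.3f)\n",
              x$mean_regression$slope, x$mean_regression$rho))
  invisible(x)
}
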