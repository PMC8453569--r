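#' Allele frequencies
#'
#' Per-SNP frequency of the counted allele, `p = mean(dosage)/2` over
#' non-missing genotypes.
#'
#' @param dataset a [genotype_dataset()].
#' @param snps SNP index subset (integer/logical), default all.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(dataset, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  d <- if (is.null(snps)) dataset$dosage else dataset$dosage[, snps, drop = FALSE]
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0)) {
    bad <- colnames(d)[n_obs == 0][1]
    abort(sprintf("SNP '%s' has no non-missing genotypes", bad),
          class = "rhmscan_grm_error")
  }
  colMeans(d, na.rm = TRUE) / 2
}

#' Build a genomic relationship matrix
#'
#' VanRaden's per-SNP-standardized ("method 2") GRM over a SNP subset:
#' `G = (1/m) * sum_i z_i z_i' / (2 p_i (1 - p_i))` with `z_i` the dosage
#' column centred at `2 p_i`. Missing dosages are mean-imputed (they
#' contribute zero to `z_i`), which keeps `G` positive semi-definite. Regional
#' GRMs are built the same way over a window's SNPs; pass the whole-genome
#' `freqs` so the per-SNP frequencies agree between the two.
#'
#' @param dataset a [genotype_dataset()].
#' @param snps SNP subset (default all).
#' @param freqs frequencies for the subset SNPs; computed from the data when
#'   `NULL`. All must satisfy `0 < p < 1`.
#' @return An `rhm_grm` object: list with `K` (the matrix), `sample_id`,
#'   `n_snps`, `snp_id`.
#' @export
build_grm <- function(dataset, snps = NULL, freqs = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  d <- if (is.null(snps)) dataset$dosage else dataset$dosage[, snps, drop = FALSE]
  if (is.null(freqs)) freqs <- allele_frequencies(dataset, snps)
  if (length(freqs) != ncol(d)) abort("freqs length must match the SNP subset")
  if (any(freqs <= 0 | freqs >= 1)) {
    bad <- colnames(d)[which(freqs <= 0 | freqs >= 1)][1]
    abort(sprintf("monomorphic SNP '%s' in GRM subset (run QC first)", bad),
          class = "rhmscan_grm_error")
  }
  m <- ncol(d)
  z <- sweep(d, 2, 2 * freqs)
  z[is.na(z)] <- 0
  w <- sweep(z, 2, sqrt(2 * freqs * (1 - freqs)), "/")
  K <- tcrossprod(w) / m
  structure(list(K = K, sample_id = dataset$sample_id, n_snps = m,
                 snp_id = colnames(d)),
            class = "rhm_grm")
}

#' @export
print.rhm_grm <- function(x, ...) {
  cat(sprintf("<rhm_grm> %d animals, %d SNPs; mean diagonal %.3f\n",
              nrow(x$K), x$n_snps, mean(diag(x$K))))
  invisible(x)
}

#' Spectral factorization of a GRM
#'
#' Symmetric eigendecomposition with small-eigenvalue truncation: eigenvalues
#' below `tol` times the largest are zeroed, defining the numerical rank and
#' the Moore-Penrose pseudo-inverse `V L+ V'`. GRMs built from fewer SNPs than
#' animals, or with frequencies estimated from the same data (which places the
#' vector of ones in the null space), are singular, so pseudo-inverse
#' semantics are used throughout instead of plain inversion.
#'
#' @param grm an `rhm_grm`.
#' @param tol relative truncation tolerance (default 1e-8).
#' @return The `rhm_grm` with elements `values` (truncated eigenvalues),
#'   `vectors`, `rank` and `tol` added.
#' @export
grm_eigen <- function(grm, tol = 1e-8) {
  stopifnot(inherits(grm, "rhm_grm"))
  if (!all(is.finite(grm$K))) {
    abort("GRM contains non-finite entries", class = "rhmscan_grm_error")
  }
  ed <- eigen(grm$K, symmetric = TRUE)
  cut <- tol * max(ed$values, 0)
  vals <- ifelse(ed$values > cut, ed$values, 0)
  grm$values <- vals
  grm$vectors <- ed$vectors
  grm$rank <- sum(vals > 0)
  grm$tol <- tol
  grm
}

#' Moore-Penrose pseudo-inverse of a GRM
#'
#' @param grm an `rhm_grm` (factorized on the fly if needed).
#' @param tol truncation tolerance passed to [grm_eigen()].
#' @return The pseudo-inverse matrix.
#' @export
grm_pseudo_inverse <- function(grm, tol = 1e-8) {
  if (is.null(grm$values)) grm <- grm_eigen(grm, tol)
  pos <- grm$values > 0
  v <- grm$vectors[, pos, drop = FALSE]
  v %*% (t(v) / grm$values[pos])
}

#' Export a GRM in GCTA text layout
#'
#' Lower-triangle pair list: indices i, j (1-based, i >= j), SNP count, value.
#' Useful for cross-checks against external GREML tools.
#'
#' @param grm an `rhm_grm`.
#' @param path output path (`.grm.gz`-style text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_grm_text <- function(grm, path) {
  n <- nrow(grm$K)
  idx <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2], m = grm$n_snps,
                    value = grm$K[idx])
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a GCTA-layout text GRM
#'
#' @param path pair-list file from [write_grm_text()].
#' @param sample_id animal identifiers in matrix order.
#' @return An `rhm_grm`.
#' @export
read_grm_text <- function(path, sample_id) {
  tab <- utils::read.table(path, col.names = c("i", "j", "m", "value"))
  n <- max(tab$i)
  if (length(sample_id) != n) abort("sample_id length does not match GRM order")
  K <- matrix(0, n, n)
  K[cbind(tab$i, tab$j)] <- tab$value
  K[cbind(tab$j, tab$i)] <- tab$value
  structure(list(K = K, sample_id = sample_id, n_snps = tab$m[1],
                 snp_id = NULL),
            class = "rhm_grm")
}
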