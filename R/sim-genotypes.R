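#' Simulate SNP genotypes
#'
#' Draws biallelic dosages per SNP as `Binomial(2, p)` with `p` uniform in the
#' configured MAF range; SNPs are in linkage equilibrium unless `ld_rho > 0`,
#' in which case the underlying gametes follow a first-order autoregressive
#' correlation along each chromosome (a crude stand-in for local LD; the scan
#' itself does not rely on it). Base-pair positions are strictly increasing
#' within each chromosome. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return A [genotype_dataset()] with the true allele frequencies attached as
#'   attribute `true_freq`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_animals
    m_per_chr <- config$snps_per_chromosome
    m <- sum(m_per_chr)
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    if (config$ld_rho > 0) {
      dosage <- .sim_dosage_ar1(n, m_per_chr, p, config$ld_rho)
    } else {
      dosage <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    }
    chrom <- rep(as.character(seq_along(m_per_chr)), m_per_chr)
    bp <- unlist(lapply(m_per_chr, function(k) cumsum(sample(1000:50000, k, replace = TRUE))),
                 use.names = FALSE)
    snp_id <- sprintf("snp_%s_%d", chrom, unlist(lapply(m_per_chr, seq_len)))
    ids <- sprintf("A%05d", seq_len(n))
    ds <- genotype_dataset(dosage,
                           map = tibble(chrom = chrom, snp_id = snp_id, bp = bp,
                                        allele_b = "B", allele_a = "A"),
                           sample_id = ids)
    attr(ds, "true_freq") <- p
    ds
  })
}

# AR(1)-correlated gametes via a latent Gaussian copula per haplotype
.sim_dosage_ar1 <- function(n, m_per_chr, p, rho) {
  m <- sum(m_per_chr)
  hap <- function() {
    z <- numeric(m)
    offset <- 0L
    for (k in m_per_chr) {
      e <- rnorm(k)
      zz <- numeric(k)
      zz[1] <- e[1]
      if (k > 1) for (i in 2:k) zz[i] <- rho * zz[i - 1] + sqrt(1 - rho^2) * e[i]
      z[offset + seq_len(k)] <- zz
      offset <- offset + k
    }
    z
  }
  out <- matrix(0L, n, m)
  thr <- stats::qnorm(p)
  for (i in seq_len(n)) {
    out[i, ] <- (hap() < thr) + (hap() < thr)
  }
  out
}

#' Simulate polygenic and regional QTL effects
#'
#' Builds per-animal true breeding values: a whole-genome polygenic value from
#' all SNPs and one regional value per configured QTL window. Per-SNP effects
#' are drawn standard normal on centred dosages, and each resulting vector is
#' rescaled so its *sample* variance equals the target variance exactly
#' (`var_u` for the polygenic part, each window's `var_v` for the regional
#' parts) — recovery tests then have a fixed truth rather than a
#' Monte-Carlo one. A window whose SNPs are all fixed cannot carry variance
#' and raises an error naming the window. One independent draw per trait.
#'
#' @param dataset a [genotype_dataset()].
#' @param config the [sim_config()] used to generate it.
#' @return A `sim_truth` object: per trait, the polygenic values `u`, a list of
#'   regional value vectors `v`, and later (after
#'   [simulate_testday_records()]) the environmental draws; plus a tibble
#'   `realized` of realized component variances.
#' @export
simulate_qtl_effects <- function(dataset, config) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  validate_sim_config(config)
  n <- nrow(dataset$dosage)
  withr::with_seed(config$seed + 1L, {
    per_trait <- lapply(config$traits, function(trait) {
      u <- .scaled_breeding_values(dataset$dosage, config$true_components[["u"]],
                                   label = "whole genome")
      v <- lapply(seq_along(config$qtl_windows), function(i) {
        w <- config$qtl_windows[[i]]
        cols <- which(dataset$map$chrom == as.character(w$chrom))[w$from:w$to]
        .scaled_breeding_values(dataset$dosage[, cols, drop = FALSE], w$var_v,
                                label = sprintf("qtl window %s:%d-%d",
                                                w$chrom, w$from, w$to))
      })
      list(u = setNames(u, dataset$sample_id), v = v)
    })
    names(per_trait) <- config$traits
    structure(list(genetic = per_trait, sample_id = dataset$sample_id,
                   config = config),
              class = "sim_truth")
  })
}

# effects on centred dosages, rescaled so sample variance hits the target
.scaled_breeding_values <- function(dosage, target_var, label) {
  mono <- apply(dosage, 2, function(x) {
    xx <- x[!is.na(x)]
    length(unique(xx)) <= 1
  })
  if (all(mono)) {
    abort(sprintf("all SNPs are monomorphic in %s; cannot carry variance", label),
          class = "rhmscan_sim_error")
  }
  if (target_var == 0) return(numeric(nrow(dosage)))
  z <- scale(dosage[, !mono, drop = FALSE], center = TRUE, scale = FALSE)
  z[is.na(z)] <- 0
  g <- drop(z %*% rnorm(ncol(z)))
  s2 <- var(g)
  if (s2 <= 0) {
    abort(sprintf("degenerate breeding values in %s", label),
          class = "rhmscan_sim_error")
  }
  g * sqrt(target_var / s2)
}
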