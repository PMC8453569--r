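#' Exact Hardy-Weinberg test
#'
#' Two-sided exact HWE p-value for one biallelic SNP: conditional on the
#' observed allele counts, the probabilities of all heterozygote counts of the
#' same parity are enumerated and those no more probable than the observed
#' configuration are summed. Computed in closed form via log-gamma; the value
#' lies in `(0, 1]`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1). Vectors
#'   are accepted and recycled element-wise.
#' @return Exact p-value(s).
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  len <- max(length(n_AA), length(n_Aa), length(n_aa))
  mapply(.hwe_exact_one, rep_len(n_AA, len), rep_len(n_Aa, len), rep_len(n_aa, len))
}

.hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) != round(c(n_AA, n_Aa, n_aa)))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("at least one genotyped individual is required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  # heterozygote counts sharing the parity of the minor-allele count
  het <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(n_Aa = k | n, nA) up to a common constant
  logp <- lgamma(n + 1) -
    lgamma((nA - het) / 2 + 1) - lgamma(het + 1) - lgamma((na - het) / 2 + 1) +
    het * log(2)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, het)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Apply genotype quality control
#'
#' SNP and sample filters in a fixed order: (1) drop SNPs off the recognised
#' autosomes; (2) drop samples with call rate not exceeding `sample_cr`;
#' (3) drop SNPs with call rate not exceeding `snp_cr`; (4) drop SNPs with
#' minor allele frequency not exceeding `maf_min`; (5) drop SNPs whose exact
#' Hardy-Weinberg p-value falls below `hwe_p`. Allele frequencies and HWE are
#' computed on the retained samples and non-missing genotypes only, so the
#' filters reflect the analysed data. Thresholds follow the strict directions
#' stated: retain call rate > 0.95, MAF > 0.02, HWE p >= 0.001.
#'
#' @param dataset a [genotype_dataset()].
#' @param sample_cr,snp_cr minimum call rates (strict `>` retention).
#' @param maf_min minimum minor allele frequency (strict `>` retention).
#' @param hwe_p HWE removal level (remove if p `<` this).
#' @param autosomes chromosome labels treated as autosomes; default `"1"` to
#'   `"26"`, the sheep autosomes.
#' @return A list with `dataset` (filtered) and `report` (per-stage tibble).
#' @export
apply_genotype_qc <- function(dataset, sample_cr = 0.95, snp_cr = 0.95,
                              maf_min = 0.02, hwe_p = 0.001,
                              autosomes = as.character(1:26)) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  stages <- list()
  note <- function(stage, entity, n_in, n_rm) {
    stages[[length(stages) + 1]] <<- tibble(stage = stage, entity = entity,
                                            n_input = n_in, n_removed = n_rm,
                                            n_retained = n_in - n_rm)
  }

  keep_snp <- dataset$map$chrom %in% autosomes
  note("autosome", "snp", ncol(dataset$dosage), sum(!keep_snp))
  ds <- subset_genotypes(dataset, snps = keep_snp)

  cr_sample <- rowMeans(!is.na(ds$dosage))
  keep_sample <- cr_sample > sample_cr
  note("sample_call_rate", "sample", nrow(ds$dosage), sum(!keep_sample))
  ds <- subset_genotypes(ds, samples = keep_sample)
  if (nrow(ds$dosage) == 0) {
    abort("all samples removed by call-rate filter; review thresholds",
          class = "rhmscan_qc_error")
  }

  cr_snp <- colMeans(!is.na(ds$dosage))
  keep_snp <- cr_snp > snp_cr
  note("snp_call_rate", "snp", ncol(ds$dosage), sum(!keep_snp))
  ds <- subset_genotypes(ds, snps = keep_snp)

  if (ncol(ds$dosage) == 0) {
    abort("all SNPs removed by QC; review thresholds", class = "rhmscan_qc_error")
  }
  freq <- colMeans(ds$dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep_snp <- maf > maf_min
  note("maf", "snp", ncol(ds$dosage), sum(!keep_snp))
  ds <- subset_genotypes(ds, snps = keep_snp)
  if (ncol(ds$dosage) == 0) {
    abort("all SNPs removed by QC; review thresholds", class = "rhmscan_qc_error")
  }

  counts <- apply(ds$dosage, 2, function(x) {
    c(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE))
  })
  pvals <- hwe_exact_pvalue(counts[1, ], counts[2, ], counts[3, ])
  keep_snp <- pvals >= hwe_p
  note("hwe", "snp", ncol(ds$dosage), sum(!keep_snp))
  ds <- subset_genotypes(ds, snps = keep_snp)

  if (ncol(ds$dosage) == 0) {
    abort("all SNPs removed by QC; review thresholds", class = "rhmscan_qc_error")
  }
  list(dataset = ds, report = dplyr::bind_rows(stages))
}

#' Serialize a QC report
#'
#' @param report a QC report tibble (from [apply_genotype_qc()] or
#'   [filter_testday_records()]).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
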