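#' Construct a genotype dataset
#'
#' Bundles a dosage matrix with its marker map and sample identifiers. The
#' dosage convention throughout the package is the count (0, 1 or 2, `NA` for
#' missing) of the *counted* allele, the one stored in the `allele_b` column of
#' the map (column 5 of a PLINK bim file). GRM sign conventions depend on this,
#' so it is fixed rather than configurable.
#'
#' @param dosage numeric matrix, animals in rows and SNPs in columns, entries
#'   in `{0, 1, 2, NA}`.
#' @param map data frame with one row per SNP and columns `chrom` (character),
#'   `snp_id`, `bp` (1-based position), `allele_b` (counted allele) and
#'   `allele_a`. Within a chromosome `bp` must be non-decreasing.
#' @param sample_id character vector of unique animal identifiers, one per
#'   dosage row.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosage`, `map` (tibble) and `sample_id`.
#' @export
genotype_dataset <- function(dosage, map, sample_id) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  map <- as_tibble(map)
  map$chrom <- as.character(map$chrom)
  required <- c("chrom", "snp_id", "bp", "allele_b", "allele_a")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0) {
    abort(paste0("marker map lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "rhmscan_format_error")
  }
  if (nrow(map) != ncol(dosage)) {
    abort(sprintf("map has %d rows but dosage has %d columns", nrow(map), ncol(dosage)),
          class = "rhmscan_format_error")
  }
  if (length(sample_id) != nrow(dosage)) {
    abort("sample_id length must equal the number of dosage rows",
          class = "rhmscan_format_error")
  }
  if (anyDuplicated(sample_id)) {
    abort("sample ids must be unique", class = "rhmscan_format_error")
  }
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    abort("dosages must be 0, 1, 2 or NA", class = "rhmscan_format_error")
  }
  decreasing <- map |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = is.unsorted(.data$bp), .groups = "drop")
  if (any(decreasing$bad)) {
    abort("bp must be non-decreasing within each chromosome",
          class = "rhmscan_format_error")
  }
  rownames(dosage) <- sample_id
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, sample_id = as.character(sample_id)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), dplyr::n_distinct(x$map$chrom)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset
#'
#' @param dataset a [genotype_dataset()].
#' @param samples logical/integer/character index of animals to keep
#'   (default all).
#' @param snps logical/integer index of SNPs to keep (default all).
#' @return A `genotype_dataset` with the selected animals and SNPs.
#' @export
subset_genotypes <- function(dataset, samples = NULL, snps = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(samples)) samples <- seq_along(dataset$sample_id)
  if (is.null(snps)) snps <- seq_len(ncol(dataset$dosage))
  genotype_dataset(dataset$dosage[samples, snps, drop = FALSE],
                   dataset$map[snps, , drop = FALSE],
                   dataset$sample_id[samples])
}
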