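# PLINK 1 binary (bed/bim/fam), SNP-major. Decoded bit-exactly: each byte
# holds four genotypes, sample order runs from the low bit pair upward.
# 2-bit codes: 00 = two copies of the counted allele (bim col 5), 10 = het,
# 11 = zero copies, 01 = missing.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# lookup: 256 bytes -> 4 dosages each, built once at load time
.bed_decode_table <- local({
  code_to_dose <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  m <- matrix(NA_real_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    codes <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    m[b + 1L, ] <- code_to_dose[as.character(codes)]
  }
  m
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam` into a
#' [genotype_dataset()]. Dosages count the allele in bim column 5 (PLINK's
#' counted allele); the PLINK missing code maps to `NA`.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) abort(paste0("missing file: ", p), class = "rhmscan_format_error")
  }
  fam <- readr::read_table(paths[3],
                           col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           col_types = "cccccc", progress = FALSE)
  bim <- readr::read_table(paths[2],
                           col_names = c("chrom", "snp_id", "cm", "bp", "allele_b", "allele_a"),
                           col_types = "ccdicc", progress = FALSE)
  if (anyDuplicated(bim$snp_id)) {
    dup <- bim$snp_id[duplicated(bim$snp_id)][1]
    abort(sprintf("duplicate SNP id '%s' in %s", dup, paths[2]),
          class = "rhmscan_format_error")
  }
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2])) {
    abort(sprintf("%s: bad magic number at offset 0", paths[1]),
          class = "rhmscan_format_error")
  }
  if (raw[3] != .bed_magic[3]) {
    abort(sprintf("%s: not SNP-major (third byte %02x)", paths[1], as.integer(raw[3])),
          class = "rhmscan_format_error")
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3 + bytes_per_snp * m
  if (length(raw) != expected) {
    abort(sprintf("%s: truncated or oversized bed (have %d bytes, expected %d)",
                  paths[1], length(raw), expected),
          class = "rhmscan_format_error")
  }
  body <- as.integer(raw[-(1:3)])
  # decode all SNPs at once: rows = byte slots within SNP, cols = SNPs
  doses <- .bed_decode_table[matrix(body + 1L, nrow = bytes_per_snp), , drop = FALSE]
  # doses: (bytes_per_snp * m) x 4; reshape to samples x snps
  dosage <- matrix(NA_real_, nrow = n, ncol = m)
  for (slot in 1:4) {
    samp <- 4L * (seq_len(bytes_per_snp) - 1L) + slot
    keep <- samp <= n
    if (!any(keep)) next
    block <- matrix(doses[, slot], nrow = bytes_per_snp)[keep, , drop = FALSE]
    dosage[samp[keep], ] <- block
  }
  genotype_dataset(dosage,
                   map = tibble(chrom = bim$chrom, snp_id = bim$snp_id, bp = bim$bp,
                                allele_b = bim$allele_b, allele_a = bim$allele_a),
                   sample_id = fam$iid)
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: emits SNP-major bed plus bim/fam. The fam file
#' stores the flock (if recorded in `flock`) as family id, otherwise the
#' sample id.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param flock optional character vector of family/flock labels per animal.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix, flock = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$dosage)
  m <- ncol(dataset$dosage)
  fid <- if (is.null(flock)) dataset$sample_id else as.character(flock)
  fam <- data.frame(fid = fid, iid = dataset$sample_id,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chrom = dataset$map$chrom, snp_id = dataset$map$snp_id,
                    cm = 0, bp = dataset$map$bp,
                    allele_b = dataset$map$allele_b, allele_a = dataset$map$allele_a)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  dose_to_code <- function(d) {
    code <- rep(1L, length(d))            # missing
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  codes <- apply(dataset$dosage, 2, dose_to_code)
  codes <- rbind(matrix(codes, nrow = n), matrix(0L, nrow = pad, ncol = m))
  dim(codes) <- c(4L, bytes_per_snp * m)
  bytes <- as.raw(colSums(codes * c(1L, 4L, 16L, 64L)))
  writeBin(bytes, con)
  invisible(prefix)
}
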