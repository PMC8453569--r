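#' Define sliding SNP windows
#'
#' Splits each chromosome of a (post-QC) marker map into windows of `size`
#' consecutive SNPs shifted by `shift`, so adjacent windows overlap by
#' `size - shift`. Full windows start at offsets `0, shift, 2*shift, ...`
#' while a complete window still fits; the SNPs after the last full window's
#' end form one non-overlapping tail window, kept only if it holds at least
#' `min_tail` SNPs (the only convention under which a "short tail" exclusion
#' rule can ever trigger). Windows never span chromosomes; a chromosome with
#' fewer than `min_tail` SNPs yields no windows and a warning.
#'
#' @param map marker map tibble (`chrom`, `snp_id`, `bp`), sorted by position
#'   within chromosome.
#' @param size window size in SNPs (default 100).
#' @param shift shift between window starts (default 50, must be <= size).
#' @param min_tail minimum SNP count for the tail window (default 25).
#' @return A tibble of windows: `chrom`, `window` (1-based ordinal per
#'   chromosome), `from`, `to` (1-based inclusive indices into the *map*,
#'   genome-wide), `n_snps`, `start_snp`, `start_bp`, `end_snp`, `end_bp`.
#' @export
make_windows <- function(map, size = 100, shift = 50, min_tail = 25) {
  if (shift > size) abort("shift must be <= size")
  map <- as_tibble(map)
  chroms <- unique(map$chrom)
  out <- purrr::map_dfr(chroms, function(ch) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < min_tail) {
      warn(sprintf("chromosome %s has only %d SNPs (< %d); no windows", ch, m, min_tail))
      return(tibble())
    }
    starts <- seq(0L, by = as.integer(shift), length.out = max(0L, (m - size) %/% shift + 1L))
    if (m < size) starts <- integer(0)
    ends <- starts + size
    last_end <- if (length(ends) > 0) max(ends) else 0L
    if (m - last_end >= min_tail) {
      starts <- c(starts, last_end)
      ends <- c(ends, m)
    }
    if (length(starts) == 0) return(tibble())
    tibble(chrom = ch,
           window = seq_along(starts),
           from = idx[starts + 1L],
           to = idx[ends],
           n_snps = ends - starts,
           start_snp = map$snp_id[idx[starts + 1L]],
           start_bp = map$bp[idx[starts + 1L]],
           end_snp = map$snp_id[idx[ends]],
           end_bp = map$bp[idx[ends]])
  })
  out
}
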