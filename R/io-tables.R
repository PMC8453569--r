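.testday_required <- c("animal_id", "flock", "test_date", "lambing_date",
                       "parity", "litter_size", "season", "dim")
.trait_cols <- c("my", "fpc", "fy", "ppc", "py")

#' Read a test-day phenotype table
#'
#' Reads the long-format TSV of repeated test-day records. Mandatory columns
#' are `animal_id flock test_date lambing_date parity litter_size season dim`;
#' trait columns (`my fpc fy ppc py` — milk yield, fat %, fat yield, protein %,
#' protein yield) are optional individually but at least one must be present.
#' Blank trait cells become `NA` and the record is kept. Dates are integer day
#' indices; `dim` is days in milk (test date minus lambing date).
#'
#' @param path TSV file with a header row.
#' @return A tibble of test-day records, row order preserved.
#' @export
read_testday_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(.testday_required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("test-day table lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rhmscan_format_error")
  }
  traits <- intersect(.trait_cols, names(tab))
  if (length(traits) == 0) {
    abort(paste0("test-day table has no trait column (any of ",
                 paste(.trait_cols, collapse = ", "), ")"),
          class = "rhmscan_format_error")
  }
  tab <- tab |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("test_date", "lambing_date",
                                                "parity", "litter_size", "season",
                                                "dim")), as.integer),
                  dplyr::across(dplyr::all_of(traits), as.numeric))
  validate_testday_table(tab)
  tab
}

#' Validate a test-day table
#'
#' Checks the structural invariants of a test-day record table: mandatory
#' columns present, parity at least 1, days-in-milk non-negative, and no
#' animal recorded twice on one date.
#'
#' @param table a data frame of test-day records.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_testday_table <- function(table) {
  missing_cols <- setdiff(.testday_required, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("test-day table lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rhmscan_format_error")
  }
  if (any(table$parity < 1, na.rm = TRUE)) {
    abort("parity must be >= 1", class = "rhmscan_format_error")
  }
  if (any(table$dim < 0, na.rm = TRUE)) {
    abort("dim (days in milk) must be >= 0", class = "rhmscan_format_error")
  }
  dup <- table |>
    dplyr::count(.data$animal_id, .data$test_date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (animal, test date) record: %s on day %s",
                  dup$animal_id[1], dup$test_date[1]),
          class = "rhmscan_format_error")
  }
  invisible(table)
}

#' Write a test-day table
#'
#' @param table a test-day record tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_testday_table <- function(table, path) {
  validate_testday_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Write window scan results
#'
#' Emits the scan result table as TSV, one row per (trait, window), sorted by
#' trait, chromosome and window ordinal, in the layout used to report
#' significant regions: window bounds as first/last SNP id and bp, the LRT,
#' its boundary-mixture p-value, the regional heritability and the
#' significance class.
#'
#' @param results a scan result tibble from [run_scan()] (or several traits'
#'   results row-bound together).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(results, path) {
  if (nrow(results) == 0) abort("no scan results to write")
  cols <- c("trait", "chrom", "window", "start_snp", "start_bp",
            "end_snp", "end_bp", "lrt", "pvalue", "h2_v", "class")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("results lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- results |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$trait, .chrom_order(.data$chrom), .data$window)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# numeric-aware chromosome ordering ("2" before "10", non-numeric labels last)
.chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), Inf, num)
}

#' Read back a scan result TSV
#'
#' @param path TSV written by [write_scan_results()].
#' @return A tibble.
#' @export
read_scan_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trait = "c", chrom = "c", window = "i", start_snp = "c", start_bp = "d",
    end_snp = "c", end_bp = "d", lrt = "d", pvalue = "d", h2_v = "d",
    class = "c"), progress = FALSE)
}
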