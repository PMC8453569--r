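#' Filter test-day records
#'
#' Applies the phenotype quality rules for repeatability test-day analyses, in
#' this order: (1) drop lactations (animal-by-parity cells) whose length — the
#' last record's days in milk — exceeds `max_lactation_days`; (2) drop
#' lactations with fewer than `min_td` records; (3) drop records missing the
#' analysed trait(s). With `trait = NULL` a record must carry *all* trait
#' columns present in the table (the pooled-analysis convention); with a
#' specific trait only that column is required, giving per-trait analysis
#' sets.
#'
#' @param table test-day tibble.
#' @param trait trait column to require, or `NULL` for all present traits.
#' @param max_lactation_days maximum lactation length retained (default 300,
#'   strict `>` removal).
#' @param min_td minimum records per lactation (default 3).
#' @return A list with `records` (the filtered tibble) and `report` (a QC
#'   report tibble itemizing removals per rule, in application order).
#' @export
filter_testday_records <- function(table, trait = NULL,
                                   max_lactation_days = 300, min_td = 3) {
  validate_testday_table(table)
  traits <- if (is.null(trait)) intersect(.trait_cols, names(table)) else trait
  missing_cols <- setdiff(traits, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown trait column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n0 <- nrow(table)

  lact_len <- table |>
    dplyr::group_by(.data$animal_id, .data$parity) |>
    dplyr::summarise(len = max(.data$dim), .groups = "drop")
  long <- lact_len |> dplyr::filter(.data$len > max_lactation_days)
  t1 <- table |> dplyr::anti_join(long, by = c("animal_id", "parity"))
  n1 <- nrow(t1)

  few <- t1 |>
    dplyr::count(.data$animal_id, .data$parity) |>
    dplyr::filter(.data$n < min_td)
  t2 <- t1 |> dplyr::anti_join(few, by = c("animal_id", "parity"))
  n2 <- nrow(t2)

  keep <- rowSums(is.na(t2[traits])) == 0
  t3 <- t2[keep, , drop = FALSE]
  n3 <- nrow(t3)

  report <- tibble(
    stage = c("lactation_length", "min_testdays", "missing_trait"),
    entity = "record",
    n_input = c(n0, n1, n2),
    n_removed = c(n0 - n1, n1 - n2, n2 - n3),
    n_retained = c(n1, n2, n3))
  list(records = t3, report = report)
}
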