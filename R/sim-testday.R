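#' Simulate repeated test-day records
#'
#' Builds the phenotype table generatively from the same model the analysis
#' fits: for record `r` of animal `a` in parity `q` at flock-by-test-day level
#' `f`, `y_r = x_r'beta + u_a + sum(v_a) + pu_a + pw_(a,q) + h_f + e_r`, with
#' `pu`, `pw`, `h`, `e` independent normal draws at the configured variances
#' and `u`, `v` taken from the genetic truth.
#'
#' The recording design mirrors flock-wise monthly milk recording: each flock
#' has its own calendar of test dates 30 days apart; every animal is recorded
#' at its flock's first `n_td` dates after lambing (`n_td` drawn uniformly
#' from `testdays_per_lactation`), so animals of a flock sampled on the same
#' date share one flock-by-test-day (FTD) level. Lambings are 330 days apart
#' across parities with a per-lactation jitter of 0–59 days, which makes
#' season of lambing (Jan–Jun vs Jul–Dec on a 364-day year) vary across
#' parities. Days in milk is test date minus lambing date and fortnight in
#' milk is `min(ceiling(dim/14), 22)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param truth a `sim_truth` from [simulate_qtl_effects()].
#' @param config the same [sim_config()].
#' @return A test-day tibble (see [read_testday_table()] for columns), with the
#'   completed truth (environmental draws and realized component variances per
#'   trait) attached as attribute `truth`.
#' @export
simulate_testday_records <- function(dataset, truth, config) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(truth, "sim_truth"))
  validate_sim_config(config)
  if (!all(dataset$sample_id %in% truth$sample_id)) {
    abort("truth lacks values for some animals", class = "rhmscan_sim_error")
  }
  withr::with_seed(config$seed + 2L, {
    n <- config$n_animals
    ids <- dataset$sample_id
    flock <- sprintf("FL%d", ((seq_len(n) - 1L) %% config$n_flocks) + 1L)
    phase <- sample(0:29, config$n_flocks, replace = TRUE)
    horizon <- config$parities_per_animal * 330L + 400L
    calendar <- lapply(seq_len(config$n_flocks),
                       function(f) seq(15L + phase[f], horizon, by = 30L))

    design <- tidyr::expand_grid(a = seq_len(n),
                                 parity = seq_len(config$parities_per_animal)) |>
      dplyr::mutate(animal_id = ids[.data$a],
                    flock = flock[.data$a],
                    offset = sample(0:59, dplyr::n(), replace = TRUE),
                    lambing_date = (.data$parity - 1L) * 330L + .data$offset,
                    litter_size = sample(1:2, dplyr::n(), replace = TRUE),
                    season = ifelse(.data$lambing_date %% 364L < 182L, 1L, 2L),
                    n_td = {
                      td_vals <- seq(config$testdays_per_lactation[1],
                                     config$testdays_per_lactation[2])
                      td_vals[sample.int(length(td_vals), dplyr::n(), replace = TRUE)]
                    })

    records <- design |>
      dplyr::mutate(fi = as.integer(sub("FL", "", .data$flock))) |>
      dplyr::rowwise() |>
      dplyr::mutate(test_date = list(utils::head(
        calendar[[.data$fi]][calendar[[.data$fi]] > .data$lambing_date],
        .data$n_td))) |>
      dplyr::ungroup() |>
      tidyr::unnest("test_date") |>
      dplyr::mutate(dim = .data$test_date - .data$lambing_date,
                    fortnight = pmin(pmax(ceiling(.data$dim / 14), 1L), 22L),
                    ftd = paste0(.data$flock, ":", .data$test_date)) |>
      dplyr::select(dplyr::all_of(c("a", "animal_id", "flock", "test_date",
                                    "lambing_date", "parity", "litter_size",
                                    "season", "dim", "fortnight", "ftd")))

    if (nrow(records) == 0) abort("no test-day records generated", class = "rhmscan_sim_error")

    fe <- config$fixed_effect_coefficients
    xbeta <- fe$intercept +
      fe$parity[pmin(records$parity, 5L)] +
      fe$litter_size[records$litter_size] +
      fe$season[records$season] +
      fe$fortnight[records$fortnight]

    comp <- config$true_components
    cells <- unique(records[c("animal_id", "parity")])
    ftd_levels <- unique(records$ftd)

    env <- list()
    realized <- list()
    for (trait in config$traits) {
      pu <- setNames(rnorm(n, 0, sqrt(comp[["pu"]])), ids)
      pw <- setNames(rnorm(nrow(cells), 0, sqrt(comp[["pw"]])),
                     paste0(cells$animal_id, ":", cells$parity))
      h <- setNames(rnorm(length(ftd_levels), 0, sqrt(comp[["h"]])), ftd_levels)
      e <- rnorm(nrow(records), 0, sqrt(comp[["e"]]))
      g <- truth$genetic[[trait]]
      u_rec <- g$u[records$animal_id]
      v_rec <- if (length(g$v) > 0) {
        rowSums(vapply(g$v, function(v) setNames(v, truth$sample_id)[records$animal_id],
                       numeric(nrow(records))))
      } else 0
      records[[trait]] <- unname(xbeta + u_rec + v_rec +
        pu[records$animal_id] +
        pw[paste0(records$animal_id, ":", records$parity)] +
        h[records$ftd] + e)
      env[[trait]] <- list(pu = pu, pw = pw, h = h, e = e)
      realized[[trait]] <- tibble(
        trait = trait,
        component = c("u", sprintf("v%d", seq_along(g$v)), "pu", "pw", "h", "e"),
        realized_var = c(var(g$u),
                         vapply(g$v, var, numeric(1)),
                         var(pu), var(pw), var(h), var(e)))
    }

    out <- records |>
      dplyr::select(dplyr::all_of(c("animal_id", "flock", "test_date",
                                    "lambing_date", "parity", "litter_size",
                                    "season", "dim")),
                    dplyr::all_of(config$traits))
    truth$env <- env
    truth$realized <- dplyr::bind_rows(realized)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_qtl_effects()] and [simulate_testday_records()] in sequence.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_dataset()]),
#'   `phenotypes` (test-day tibble) and `truth` (`sim_truth`).
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  truth <- simulate_qtl_effects(geno, config)
  pheno <- simulate_testday_records(geno, truth, config)
  list(genotypes = geno, phenotypes = pheno, truth = attr(pheno, "truth"))
}

#' Write a simulated dataset to disk
#'
#' Emits a PLINK 1 bed/bim/fam triple, the test-day table as TSV, and the
#' truth record (breeding values, environmental draws, realized variances) as
#' JSON, so a simulation can be re-read through the standard readers.
#'
#' @param dataset a [genotype_dataset()].
#' @param table the test-day tibble (with or without its `truth` attribute).
#' @param directory output directory (created if needed).
#' @param basename file stem, default `"sim"`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixture <- function(dataset, table, directory, basename = "sim") {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  prefix <- file.path(directory, basename)
  flock <- table$flock[match(dataset$sample_id, table$animal_id)]
  flock[is.na(flock)] <- "0"
  write_plink(dataset, prefix, flock = flock)
  write_testday_table(table, paste0(prefix, "_testday.tsv"))
  paths <- c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
             fam = paste0(prefix, ".fam"),
             testday = paste0(prefix, "_testday.tsv"))
  truth <- attr(table, "truth")
  if (!is.null(truth)) {
    truth_path <- paste0(prefix, "_truth.json")
    jsonlite::write_json(
      list(sample_id = truth$sample_id,
           genetic = truth$genetic,
           realized = truth$realized),
      truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}
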