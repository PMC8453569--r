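#' Build a model frame for the repeatability test-day model
#'
#' Assembles the response, fixed-effect design and random-effect terms for one
#' trait. Fixed effects are intercept plus treatment-coded parity (parities
#' above 5 collapsed to level 5), litter size (2 levels), season of lambing
#' (2 levels) and fortnight in milk (`min(ceiling(dim/14), 22)`, 22 levels);
#' columns that are linearly dependent in the observed data are dropped and
#' recorded. Random terms, in order: `u` — animal additive genomic effect with
#' the GRM as covariance; `pu` — permanent environment of the animal across
#' lactations (identity); `pw` — permanent environment within an
#' animal-by-parity cell (identity); `h` — flock-by-test-day interaction
#' (identity); plus, when `regional_grm` is given, `v` — the regional additive
#' effect with the regional GRM as covariance. The residual is implicit.
#'
#' @param table QC'd test-day tibble (no missing values in `trait`).
#' @param trait response column name.
#' @param grm whole-genome `rhm_grm` covering every animal in `table`.
#' @param regional_grm optional regional `rhm_grm` (same animals).
#' @return An `rhm_model_frame`: list with `y`, `X`, `terms` (per-term level
#'   maps and covariance matrices), dense relationship matrices `M` used by
#'   the likelihood, `n`, `p`, `dropped_columns`, `trait`.
#' @export
build_model_frame <- function(table, trait, grm, regional_grm = NULL) {
  validate_testday_table(table)
  stopifnot(inherits(grm, "rhm_grm"))
  if (!trait %in% names(table)) {
    abort(sprintf("unknown trait '%s'", trait))
  }
  if (anyNA(table[[trait]])) {
    abort(sprintf("trait '%s' has missing values; run filter_testday_records first", trait))
  }
  absent <- setdiff(unique(table$animal_id), grm$sample_id)
  if (length(absent) > 0) {
    abort(paste0("animals absent from GRM: ",
                 paste(utils::head(absent, 5), collapse = ", "),
                 if (length(absent) > 5) sprintf(" (+%d more)", length(absent) - 5) else ""),
          class = "rhmscan_model_error")
  }

  y <- as.numeric(table[[trait]])
  parity5 <- factor(pmin(table$parity, 5L), levels = 1:5)
  litter <- factor(table$litter_size, levels = 1:2)
  season <- factor(table$season, levels = 1:2)
  fim <- factor(pmin(pmax(ceiling(table$dim / 14), 1L), 22L), levels = 1:22)
  X <- stats::model.matrix(~ parity5 + litter + season + fim)

  qrX <- qr(X, LAPACK = TRUE)
  rank <- sum(abs(diag(qr.R(qrX))) > 1e-10 * max(abs(diag(qr.R(qrX)))))
  keep <- sort(qrX$pivot[seq_len(rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, keep, drop = FALSE]

  animal_idx <- match(table$animal_id, grm$sample_id)
  pw_level <- as.integer(factor(paste0(table$animal_id, ":", pmin(table$parity, 5L))))
  ftd_level <- as.integer(factor(paste0(table$flock, ":", table$test_date)))

  terms <- list(
    u = list(map = animal_idx, C = grm$K, n_levels = length(grm$sample_id)),
    pu = list(map = animal_idx, C = NULL, n_levels = length(grm$sample_id)),
    pw = list(map = pw_level, C = NULL, n_levels = max(pw_level)),
    h = list(map = ftd_level, C = NULL, n_levels = max(ftd_level)))
  if (!is.null(regional_grm)) {
    stopifnot(inherits(regional_grm, "rhm_grm"))
    if (!identical(regional_grm$sample_id, grm$sample_id)) {
      abort("regional GRM sample order differs from the whole-genome GRM",
            class = "rhmscan_model_error")
    }
    terms$v <- list(map = animal_idx, C = regional_grm$K,
                    n_levels = length(grm$sample_id))
  }

  M <- lapply(terms, function(tr) {
    if (is.null(tr$C)) {
      outer(tr$map, tr$map, "==") * 1
    } else {
      tr$C[tr$map, tr$map, drop = FALSE]
    }
  })

  structure(list(y = y, X = X, terms = terms, M = M,
                 n = length(y), p = ncol(X),
                 dropped_columns = dropped, trait = trait),
            class = "rhm_model_frame")
}

#' Add a regional term to a fitted frame
#'
#' Cheap construction of the full (H1) frame from the null frame of the same
#' records: reuses the response, design and background relationship matrices,
#' adding only the regional covariance.
#'
#' @param frame an `rhm_model_frame` without a `v` term.
#' @param regional_grm regional `rhm_grm` over the same animals (same order as
#'   the `u` term's GRM).
#' @return The extended `rhm_model_frame`.
#' @export
add_regional_term <- function(frame, regional_grm) {
  stopifnot(inherits(frame, "rhm_model_frame"), inherits(regional_grm, "rhm_grm"))
  if ("v" %in% names(frame$terms)) abort("frame already has a regional term")
  map <- frame$terms$u$map
  frame$terms$v <- list(map = map, C = regional_grm$K,
                        n_levels = frame$terms$u$n_levels)
  frame$M$v <- regional_grm$K[map, map, drop = FALSE]
  frame
}

#' @export
print.rhm_model_frame <- function(x, ...) {
  cat(sprintf("<rhm_model_frame> trait '%s': %d records, %d fixed-effect columns\n",
              x$trait, x$n, x$p))
  cat("  random terms:", paste(sprintf("%s(%d)", names(x$terms),
                                       vapply(x$terms, function(t) t$n_levels, 1L)),
                               collapse = ", "), "+ residual\n")
  if (length(x$dropped_columns) > 0) {
    cat("  dropped fixed columns:", paste(x$dropped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}
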