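#' Run a regional heritability scan
#'
#' For one trait: fits the null repeatability test-day model once (additive
#' genomic + permanent environment across/within lactation + flock-by-test-day
#' + residual), then for every window builds the regional GRM from the
#' window's SNPs, refits with the extra regional variance (warm-started from
#' the null estimates with the regional variance at 1% of the phenotypic
#' variance), and reports the LRT against the boundary-mixture null, the
#' regional heritability `h2_v` and the significance class. Windows whose full
#' fit fails to converge are retained with `converged = FALSE`, never dropped.
#' Windows are evaluated independently, so results do not depend on their
#' order.
#'
#' @param dataset post-QC [genotype_dataset()].
#' @param table post-QC test-day tibble.
#' @param trait response column name.
#' @param windows window tibble from [make_windows()]; computed from the map
#'   with the default 100/50/25 scheme when `NULL`.
#' @param alpha genome-wide significance level for the thresholds.
#' @param grm optional precomputed whole-genome `rhm_grm` (built from all SNPs
#'   when `NULL`).
#' @param null_fit optional precomputed null `rhm_fit` for this trait.
#' @param exclude_region_from_background if `TRUE`, the whole-genome GRM used
#'   for each window's full model is rebuilt without that window's SNPs;
#'   default `FALSE` (the background GRM uses all SNPs, so window SNPs appear
#'   in both `G` and the regional GRM).
#' @param consistent_mixture passed to [scan_thresholds()].
#' @param max_iter,tol REML controls, see [fit_reml()].
#' @param verbose print per-window progress.
#' @return An `rhm_scan` tibble: one row per window with `trait`, window
#'   coordinates, `loglik_null`, `loglik_full`, `lrt`, `clamped`, `pvalue`,
#'   `var_v`, `h2_v`, `converged`, `class`; thresholds and the null fit are
#'   attached as attributes `thresholds` and `null_fit`.
#' @export
run_scan <- function(dataset, table, trait, windows = NULL, alpha = 0.05,
                     grm = NULL, null_fit = NULL,
                     exclude_region_from_background = FALSE,
                     consistent_mixture = FALSE,
                     max_iter = 200, tol = 1e-6, verbose = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(windows)) windows <- make_windows(dataset$map)
  if (nrow(windows) == 0) abort("no windows to scan")
  freqs <- allele_frequencies(dataset)
  if (is.null(grm)) grm <- build_grm(dataset, freqs = freqs)
  null_frame <- build_model_frame(table, trait, grm)
  if (is.null(null_fit)) null_fit <- fit_reml(null_frame, max_iter = max_iter, tol = tol)
  thresholds <- scan_thresholds(nrow(windows), alpha = alpha,
                                consistent_mixture = consistent_mixture)

  init_full <- c(null_fit$components[c("u", "pu", "pw", "h")],
                 v = unname(0.01 * null_fit$var_p),
                 e = unname(null_fit$components["e"]))

  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    snp_idx <- seq(w$from, w$to)
    grm_v <- build_grm(dataset, snps = snp_idx, freqs = freqs[snp_idx])
    if (exclude_region_from_background) {
      bg <- build_grm(dataset, snps = setdiff(seq_len(ncol(dataset$dosage)), snp_idx),
                      freqs = freqs[-snp_idx])
      frame_full <- build_model_frame(table, trait, bg, regional_grm = grm_v)
    } else {
      frame_full <- add_regional_term(null_frame, grm_v)
    }
    fit_full <- fit_reml(frame_full, init = init_full, max_iter = max_iter, tol = tol)
    stat <- lrt_statistic(fit_full, null_fit)
    if (verbose) {
      message(sprintf("window %s:%d  LRT = %.3f", w$chrom, w$window, as.numeric(stat)))
    }
    tibble(trait = trait, chrom = w$chrom, window = w$window,
           from = w$from, to = w$to, n_snps = w$n_snps,
           start_snp = w$start_snp, start_bp = w$start_bp,
           end_snp = w$end_snp, end_bp = w$end_bp,
           loglik_null = null_fit$loglik, loglik_full = fit_full$loglik,
           lrt = as.numeric(stat), clamped = attr(stat, "clamped"),
           pvalue = mixture_pvalue(as.numeric(stat)),
           var_v = unname(fit_full$components["v"]),
           h2_v = unname(fit_full$components["v"] / fit_full$var_p),
           converged = fit_full$converged)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.chrom_order(.data$chrom), .data$window)
  out <- classify_results(out, thresholds)
  attr(out, "thresholds") <- thresholds
  attr(out, "null_fit") <- null_fit
  class(out) <- c("rhm_scan", class(out))
  out
}

#' Manhattan-style plot of a scan
#'
#' LRT against genomic position (window midpoint), one panel colouring per
#' chromosome, with the genome-wide (solid) and suggestive (dashed) threshold
#' lines.
#'
#' @param object an `rhm_scan` result.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rhm_scan <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- as_tibble(object) |>
    dplyr::mutate(mid_bp = (.data$start_bp + .data$end_bp) / 2,
                  chrom_n = .chrom_order(.data$chrom)) |>
    dplyr::arrange(.data$chrom_n, .data$mid_bp) |>
    dplyr::group_by(.data$chrom_n) |>
    dplyr::mutate(chrom_span = max(.data$mid_bp)) |>
    dplyr::ungroup()
  offsets <- df |>
    dplyr::distinct(.data$chrom_n, .data$chrom_span) |>
    dplyr::arrange(.data$chrom_n) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$chrom_span), default = 0))
  df <- df |>
    dplyr::left_join(offsets[c("chrom_n", "offset")], by = "chrom_n") |>
    dplyr::mutate(pos = .data$mid_bp + .data$offset,
                  chrom_f = factor(.data$chrom, levels = unique(.data$chrom)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$lrt,
                                        colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 1.2, show.legend = FALSE) +
    ggplot2::labs(x = "genomic position", y = "LRT",
                  title = unique(df$trait)) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thr$genomewide, linetype = "solid") +
      ggplot2::geom_hline(yintercept = thr$suggestive, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.rhm_scan
#' @param scan an `rhm_scan` result.
#' @export
plot_scan <- function(scan) autoplot.rhm_scan(scan)

#' Window plot data
#'
#' The per-window plot table (window midpoint bp vs LRT) used by the
#' Manhattan-style plot, for export alongside the results TSV.
#'
#' @param scan an `rhm_scan` result.
#' @return A tibble with `trait`, `chrom`, `window`, `mid_bp`, `lrt`, `class`.
#' @export
scan_plot_data <- function(scan) {
  as_tibble(scan) |>
    dplyr::transmute(.data$trait, .data$chrom, .data$window,
                     mid_bp = (.data$start_bp + .data$end_bp) / 2,
                     .data$lrt, .data$class)
}
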