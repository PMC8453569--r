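#' Scan significance thresholds
#'
#' Multiple-testing thresholds for a window scan in which consecutive windows
#' overlap by half, so `n_windows` windows are counted as `T = n_windows / 2`
#' effective tests. Two conventions are combined by default:
#'
#' * genome-wide: the LRT `x` solving `0.5 Pr(chi2_1 >= x) = alpha / T`
#'   (Bonferroni under the boundary mixture);
#' * suggestive (one expected false positive per scan): the `x` solving
#'   `Pr(chi2_1 >= x) = 1 / T` (plain chi-square-1 tail).
#'
#' This mixed pairing is the convention that reproduces both customary
#' published threshold values for an 827-window ovine scan (13.48 and 9.20);
#' set `consistent_mixture = TRUE` to use the boundary mixture for the
#' suggestive level as well (`0.5 Pr(chi2_1 >= x) = 1 / T`).
#'
#' @param n_windows realized number of windows in the scan (>= 2).
#' @param alpha genome-wide type-I error level.
#' @param consistent_mixture use the mixture tail for the suggestive level.
#' @return A `scan_thresholds` list: `n_windows`, `effective_tests`,
#'   `genomewide` and `suggestive` LRT thresholds, and their per-test
#'   significance levels `genomewide_p`, `suggestive_p`.
#' @export
scan_thresholds <- function(n_windows, alpha = 0.05, consistent_mixture = FALSE) {
  if (n_windows < 2) abort("n_windows must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  T_eff <- n_windows / 2
  gw_p <- alpha / T_eff
  sug_p <- 1 / T_eff
  gw <- qchisq(min(1, 2 * gw_p), df = 1, lower.tail = FALSE)
  sug <- if (consistent_mixture) {
    qchisq(min(1, 2 * sug_p), df = 1, lower.tail = FALSE)
  } else {
    qchisq(min(1, sug_p), df = 1, lower.tail = FALSE)
  }
  structure(list(n_windows = n_windows, effective_tests = T_eff,
                 genomewide = gw, suggestive = sug,
                 genomewide_p = gw_p, suggestive_p = sug_p,
                 consistent_mixture = consistent_mixture),
            class = "scan_thresholds")
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat(sprintf("<scan_thresholds> %d windows counted as %.1f tests\n",
              x$n_windows, x$effective_tests))
  cat(sprintf("  genome-wide LRT > %.2f (per-test p = %.3g, -log10 = %.2f)\n",
              x$genomewide, x$genomewide_p, -log10(x$genomewide_p)))
  cat(sprintf("  suggestive  LRT > %.2f (per-test p = %.3g, -log10 = %.2f)\n",
              x$suggestive, x$suggestive_p, -log10(x$suggestive_p)))
  invisible(x)
}

#' Classify scan results against thresholds
#'
#' Assigns each window the class `"genomewide"` if its LRT strictly exceeds
#' the genome-wide threshold, else `"suggestive"` if it strictly exceeds the
#' suggestive threshold, else `"none"`.
#'
#' @param results scan result tibble with an `lrt` column.
#' @param thresholds a [scan_thresholds()] object.
#' @return `results` with the `class` column (re)computed.
#' @export
classify_results <- function(results, thresholds) {
  stopifnot(inherits(thresholds, "scan_thresholds"))
  results$class <- dplyr::case_when(
    results$lrt > thresholds$genomewide ~ "genomewide",
    results$lrt > thresholds$suggestive ~ "suggestive",
    .default = "none")
  results
}
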