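#' Variance ratios from component values
#'
#' Pure ratio arithmetic on a table of variance components, one row per trait:
#' heritability `h2 = var_u / var_p`, regional heritability
#' `h2_v = var_v / var_p`, repeatability across lactations
#' `r_acr = (var_u + var_pu) / var_p`, repeatability within lactation
#' `r_wit = (var_u + var_pu + var_pw) / var_p`, and the flock-by-test-day
#' ratio `ftd2 = var_h / var_p`. The phenotypic variance `var_p` is the sum of
#' all components; supply it directly (column `var_p`) when the residual
#' variance is not available, as in published component tables.
#'
#' @param components data frame with columns `var_u`, `var_pu`, `var_pw`,
#'   `var_h` and either `var_e` (and optionally `var_v`) or `var_p`; an
#'   optional identifier column (e.g. `trait`) is carried through.
#' @return The input tibble with `var_p`, `h2`, `h2_v` (if regional), `r_acr`,
#'   `r_wit`, `ftd2` appended.
#' @export
variance_ratios <- function(components) {
  components <- as_tibble(components)
  need <- c("var_u", "var_pu", "var_pw", "var_h")
  missing_cols <- setdiff(need, names(components))
  if (length(missing_cols) > 0) {
    abort(paste0("components lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"var_p" %in% names(components)) {
    if (!"var_e" %in% names(components)) {
      abort("supply either var_e or var_p")
    }
    vv <- if ("var_v" %in% names(components)) components$var_v else 0
    components$var_p <- components$var_u + components$var_pu +
      components$var_pw + components$var_h + components$var_e + vv
  }
  if (any(components$var_p <= 0)) {
    abort("phenotypic variance must be positive", class = "rhmscan_reml_error")
  }
  out <- components |>
    dplyr::mutate(h2 = .data$var_u / .data$var_p,
                  r_acr = (.data$var_u + .data$var_pu) / .data$var_p,
                  r_wit = (.data$var_u + .data$var_pu + .data$var_pw) / .data$var_p,
                  ftd2 = .data$var_h / .data$var_p)
  if ("var_v" %in% names(components)) {
    out$h2_v <- components$var_v / components$var_p
  }
  out
}

#' Ratios with delta-method standard errors from a fit
#'
#' Computes the derived ratios of an [fit_reml()] result together with
#' first-order (delta-method) standard errors propagated through the inverse
#' average-information matrix.
#'
#' @param fit an `rhm_fit`.
#' @return A tibble with one row per ratio: `ratio`, `estimate`, `se`.
#' @export
derived_ratios <- function(fit) {
  stopifnot(inherits(fit, "rhm_fit"))
  theta <- fit$components
  tot <- sum(theta)
  if (tot <= 0) abort("zero phenotypic variance", class = "rhmscan_reml_error")
  cov_theta <- tryCatch(solve(fit$AI), error = function(e) NULL)
  nm <- names(theta)
  ratio_sets <- list(h2 = "u", r_acr = c("u", "pu"), r_wit = c("u", "pu", "pw"),
                     ftd2 = "h")
  if ("v" %in% nm) ratio_sets$h2_v <- "v"
  purrr::imap_dfr(ratio_sets, function(set, label) {
    num <- sum(theta[set])
    est <- num / tot
    se <- NA_real_
    if (!is.null(cov_theta)) {
      grad <- (as.numeric(nm %in% set) * tot - num) / tot^2
      v <- drop(t(grad) %*% cov_theta %*% grad)
      se <- if (v >= 0) sqrt(v) else NA_real_
    }
    tibble(ratio = label, estimate = est, se = se)
  })
}

#' @describeIn fit_reml Broom-style component table: one row per variance
#'   component (including the residual) with estimate and standard error,
#'   followed by the derived ratios.
#' @param x an `rhm_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.rhm_fit <- function(x, ...) {
  comp <- tibble(term = names(x$components),
                 type = "variance",
                 estimate = unname(x$components),
                 se = unname(x$SE),
                 boundary = unname(x$boundary))
  rat <- derived_ratios(x) |>
    dplyr::transmute(term = .data$ratio, type = "ratio",
                     estimate = .data$estimate, se = .data$se,
                     boundary = FALSE)
  dplyr::bind_rows(comp, rat)
}

#' @describeIn fit_reml Broom-style one-row fit summary.
#' @exportS3Method generics::glance
glance.rhm_fit <- function(x, ...) {
  tibble(trait = x$trait, n = x$n, p = x$p,
         logLik = x$loglik, var_p = x$var_p,
         converged = x$converged, iterations = x$iterations,
         gradient_norm = x$gradient_norm)
}

#' Likelihood-ratio statistic between nested fits
#'
#' `LRT = 2 (logL_full - logL_null)`, clamped to zero when numerical noise
#' makes it marginally negative (the clamp is recorded in attribute
#' `clamped`). The two fits must be the same model frame apart from the
#' regional term.
#'
#' @param full fit of the model including the regional variance.
#' @param null fit of the model without it.
#' @return The LRT statistic with attribute `clamped`.
#' @export
lrt_statistic <- function(full, null) {
  stopifnot(inherits(full, "rhm_fit"), inherits(null, "rhm_fit"))
  if (full$n != null$n || full$p != null$p ||
      !identical(setdiff(full$term_names, "v"), null$term_names)) {
    abort("fits are not a nested full/null pair on the same frame",
          class = "rhmscan_reml_error")
  }
  stat <- 2 * (full$loglik - null$loglik)
  clamped <- stat < 0
  if (clamped) stat <- 0
  structure(stat, clamped = clamped)
}

#' Boundary-mixture p-value for a regional LRT
#'
#' A variance tested on the boundary of its parameter space has the
#' `0.5 chi2_0 + 0.5 chi2_1` mixture as its null distribution: the p-value is
#' 1 at `LRT = 0` and `0.5 Pr(chi2_1 >= LRT)` otherwise.
#'
#' @param lrt non-negative LRT statistic(s).
#' @return p-value(s) in `(0, 1]`.
#' @export
mixture_pvalue <- function(lrt) {
  if (any(lrt < 0)) abort("LRT must be >= 0")
  ifelse(lrt == 0, 1, 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
}
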