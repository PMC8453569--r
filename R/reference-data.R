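#' Reference milk-trait tables
#'
#' Published summary tables for the five test-day milk traits (milk yield MY,
#' fat percentage F_PCT, fat yield FY, protein percentage P_PCT, protein yield
#' PY) of a Valle del Belice dairy-sheep population, bundled as plain TSV:
#'
#' * `"components"` — REML variance components (additive genomic `var_u`,
#'   permanent environment across `var_pu` and within `var_pw` lactations,
#'   flock-by-test-day `var_h`, phenotypic `var_p`) with the published ratio
#'   estimates and standard errors;
#' * `"descriptives"` — record counts, mean, SD, CV(%) and range per trait.
#'
#' These are reported (rounded) values, used to validate the package's ratio
#' and CV arithmetic against an external analysis; they are not computable
#' from the synthetic data.
#'
#' @param which `"components"` or `"descriptives"`.
#' @return A tibble.
#' @export
milk_trait_reference <- function(which = c("components", "descriptives")) {
  which <- match.arg(which)
  fname <- switch(which,
                  components = "milk_trait_components.tsv",
                  descriptives = "milk_trait_descriptives.tsv")
  path <- system.file("extdata", fname, package = "rhmscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
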