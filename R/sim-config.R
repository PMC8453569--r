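#' Simulation configuration
#'
#' Describes a synthetic dairy-sheep dataset with the statistical structure the
#' repeatability test-day model assumes: biallelic SNPs in linkage equilibrium
#' on autosomes, a handful of flocks sharing monthly recording dates, up to
#' five parities per ewe with several test-day records per lactation, and
#' phenotypes built generatively as fixed effects plus additive genomic,
#' regional (QTL window), permanent environment (across and within lactation),
#' flock-by-test-day and residual terms.
#'
#' Defaults emulate the motivating study design: ~480 ewes in 4 flocks
#' genotyped at ~37k SNPs on 26 autosomes, 3–10 monthly records per lactation,
#' and variance proportions (on a unit phenotypic variance)
#' `u = 0.11, pu = 0.07, pw = 0.06, h = 0.40, e = 0.36` — the fat-percentage
#' pattern, where flock-by-test-day dominates. The upper record count is 10 so
#' that monthly recording keeps lactations within the 300-day QC bound.
#'
#' @param n_animals number of ewes (>= 2).
#' @param snps_per_chromosome integer vector, SNPs per simulated autosome;
#'   chromosomes are labelled `"1"`, `"2"`, ...
#' @param maf_range allele-frequency range `(lo, hi]` in `(0, 0.5]` from which
#'   per-SNP frequencies are drawn uniformly.
#' @param true_components named numeric: generative variances `u` (additive
#'   genomic), `pu` (permanent env across lactations), `pw` (permanent env
#'   within parity), `h` (flock-by-test-day), `e` (residual). All >= 0.
#' @param qtl_windows list of QTL window specs, each
#'   `list(chrom =, from =, to =, var_v =)` with `from`/`to` 1-based inclusive
#'   SNP indices *within* that chromosome and `var_v` the regional variance.
#' @param n_flocks number of flocks.
#' @param parities_per_animal parities simulated for every animal (max 5).
#' @param testdays_per_lactation integer range `c(lo, hi)` of records per
#'   lactation.
#' @param fixed_effect_coefficients named list of effect vectors: `parity`
#'   (5), `litter_size` (2), `season` (2), `fortnight` (22) and scalar
#'   `intercept`. Defaults give a mild parity trend and a declining lactation
#'   curve on a unit-variance trait; set [zero_fixed_effects()] for pure
#'   variance-component studies.
#' @param traits trait columns to simulate (independent draws with identical
#'   variance structure).
#' @param ld_rho optional autoregressive correlation between adjacent SNPs
#'   (0 = linkage equilibrium, the default).
#' @param seed integer seed; every simulation function derives its stream from
#'   it, so a config is fully reproducible.
#'
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_animals = 480,
                       snps_per_chromosome = rep(1430L, 26),
                       maf_range = c(0.02, 0.5),
                       true_components = c(u = 0.11, pu = 0.07, pw = 0.06,
                                           h = 0.40, e = 0.36),
                       qtl_windows = list(),
                       n_flocks = 4,
                       parities_per_animal = 3,
                       testdays_per_lactation = c(3L, 10L),
                       fixed_effect_coefficients = default_fixed_effects(),
                       traits = c("my", "fpc", "fy", "ppc", "py"),
                       ld_rho = 0,
                       seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              maf_range = as.numeric(maf_range),
              true_components = true_components,
              qtl_windows = qtl_windows,
              n_flocks = as.integer(n_flocks),
              parities_per_animal = as.integer(parities_per_animal),
              testdays_per_lactation = as.integer(rep(testdays_per_lactation,
                                                      length.out = 2)),
              fixed_effect_coefficients = fixed_effect_coefficients,
              traits = traits,
              ld_rho = as.numeric(ld_rho),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_fixed_effects <- function() {
  list(intercept = 1,
       parity = c(0, 0.10, 0.15, 0.15, 0.12),
       litter_size = c(0, -0.08),
       season = c(0, 0.05),
       fortnight = 0.25 * exp(-(1:22) / 8) - 0.01 * (1:22))
}

#' @rdname sim_config
#' @export
zero_fixed_effects <- function() {
  list(intercept = 0, parity = numeric(5), litter_size = numeric(2),
       season = numeric(2), fortnight = numeric(22))
}

validate_sim_config <- function(cfg) {
  if (cfg$n_animals < 2) abort("n_animals must be >= 2", class = "rhmscan_config_error")
  if (any(cfg$snps_per_chromosome < 1)) {
    abort("every chromosome needs at least 1 SNP", class = "rhmscan_config_error")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || any(!is.finite(mr)) || mr[1] <= 0 || mr[2] > 0.5 ||
      mr[1] > mr[2]) {
    abort("maf_range must lie within (0, 0.5] with lo <= hi",
          class = "rhmscan_config_error")
  }
  comp <- cfg$true_components
  need <- c("u", "pu", "pw", "h", "e")
  if (!all(need %in% names(comp))) {
    abort(paste0("true_components needs entries ", paste(need, collapse = ", ")),
          class = "rhmscan_config_error")
  }
  if (any(comp < 0)) abort("variances must be >= 0", class = "rhmscan_config_error")
  if (cfg$parities_per_animal < 1 || cfg$parities_per_animal > 5) {
    abort("parities_per_animal must be in 1..5", class = "rhmscan_config_error")
  }
  if (any(cfg$testdays_per_lactation < 1)) {
    abort("testdays_per_lactation must be >= 1", class = "rhmscan_config_error")
  }
  for (w in cfg$qtl_windows) {
    if (!all(c("chrom", "from", "to", "var_v") %in% names(w))) {
      abort("each qtl window needs chrom, from, to, var_v",
            class = "rhmscan_config_error")
    }
    ci <- match(as.character(w$chrom), as.character(seq_along(cfg$snps_per_chromosome)))
    if (is.na(ci)) {
      abort(sprintf("qtl window on unknown chromosome '%s'", w$chrom),
            class = "rhmscan_config_error")
    }
    if (w$from < 1 || w$to > cfg$snps_per_chromosome[ci] || w$from > w$to) {
      abort(sprintf("qtl window %s:%d-%d outside chromosome (1-%d)",
                    w$chrom, w$from, w$to, cfg$snps_per_chromosome[ci]),
            class = "rhmscan_config_error")
    }
    if (w$var_v < 0) abort("qtl var_v must be >= 0", class = "rhmscan_config_error")
  }
  invisible(cfg)
}
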