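Package: rhmscan
Title: Regional Heritability Mapping for Repeated-Record Dairy Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Regional heritability mapping (RHM) of quantitative traits with
    repeated records, as used for test-day milk traits in dairy sheep. Fits a
    repeatability test-day animal model with additive genomic, permanent
    environment (across and within lactation), flock-by-test-day and residual
    random effects by average-information REML on VanRaden genomic relationship
    matrices, then scans the genome in sliding windows of consecutive SNPs,
    testing each window's regional variance by a likelihood ratio against a
    one-half chi-square(0) plus one-half chi-square(1) boundary mixture with
    Bonferroni-style genome-wide and suggestive thresholds. Includes SNP and
    phenotype quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), PLINK 1 binary input/output, and a synthetic-data
    generator with known truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
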