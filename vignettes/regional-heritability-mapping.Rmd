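---
title: "Regional heritability mapping for repeated-record dairy traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping for repeated-record dairy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP association scans in small, structured livestock populations are
underpowered: a locus whose variants each explain little variance never
clears a genome-wide threshold, even when the locus as a whole matters.
Regional heritability mapping (RHM) tests the *variance explained by a
window of consecutive SNPs* instead. A genomic relationship matrix (GRM)
built from the window's SNPs defines a regional additive effect, its
variance is estimated by REML inside the full model, and a likelihood-ratio
test asks whether that regional variance is zero. `rhmscan` implements this
pipeline for repeated-record ("test-day") dairy traits — the setting of
milk recording in dairy sheep, where each ewe contributes several
measurements per lactation over several lactations and management structure
(flock, recording date) dominates the phenotypic variance.

## The model

For a test-day record $y$ of animal $a$ in parity $q$:

$$y = \mathbf{x}'\boldsymbol\beta + u_a + v_a + pu_a + pw_{aq} + h_f + e$$

with fixed effects $\boldsymbol\beta$ — parity (5 classes, higher parities
collapsed into class 5), litter size (single/multiple), season of lambing
(January–June vs July–December), and fortnight in milk
$\min(\lceil \mathrm{DIM}/14 \rceil, 22)$ (22 classes) — and independent
random effects

* $u \sim N(0, \mathbf{G}\sigma^2_u)$: additive genomic, $\mathbf{G}$ the
  whole-genome GRM;
* $v \sim N(0, \mathbf{G}_v\sigma^2_v)$: the regional additive effect,
  $\mathbf{G}_v$ the GRM of the window under test (absent from the null
  model);
* $pu \sim N(0, \mathbf{I}\sigma^2_{pu})$: permanent environment of the
  animal across lactations;
* $pw \sim N(0, \mathbf{I}\sigma^2_{pw})$: permanent environment within an
  animal-by-parity cell;
* $h \sim N(0, \mathbf{I}\sigma^2_h)$: flock-by-test-day (FTD) interaction,
  one level per flock and recording date;
* $e \sim N(0, \mathbf{I}\sigma^2_e)$: residual.

The phenotypic variance is the component sum
$\sigma^2_p = \sigma^2_u + \sigma^2_v + \sigma^2_{pu} + \sigma^2_{pw} +
\sigma^2_h + \sigma^2_e$, and the reported ratios are
$h^2 = \sigma^2_u/\sigma^2_p$, $h^2_v = \sigma^2_v/\sigma^2_p$,
repeatability across lactations
$r_{acr} = (\sigma^2_u+\sigma^2_{pu})/\sigma^2_p$, within lactation
$r_{wit} = (\sigma^2_u+\sigma^2_{pu}+\sigma^2_{pw})/\sigma^2_p$, and
$\mathrm{FTD}^2 = \sigma^2_h/\sigma^2_p$. Standard errors of ratios come
from first-order (delta-method) propagation through the inverse
average-information matrix; the SE method behind published tables of this
kind is rarely stated, and the delta method is the conventional choice.

## GRM construction

`build_grm()` uses the per-SNP-standardized VanRaden estimator ("method 2"):

$$\mathbf{G} = \frac{1}{m}\sum_{i=1}^{m}
  \frac{\mathbf{z}_i\mathbf{z}_i'}{2p_i(1-p_i)},$$

with $\mathbf{z}_i$ the dosage column centred at $2p_i$. Dosages count the
allele in column 5 of the bim file; missing dosages are mean-imputed
(contributing zero to $\mathbf{z}_i$), which preserves positive
semi-definiteness. Regional GRMs use the same estimator restricted to the
window's SNPs, with the *same* per-SNP frequencies as the whole-genome
matrix, estimated once from the post-QC data. Because frequencies are
estimated from the data, the vector of ones lies in the null space of
$\mathbf{G}$ — the matrix is always singular — so spectral utilities
(`grm_eigen()`, `grm_pseudo_inverse()`) use eigenvalue truncation at
`tol = 1e-8` relative to the largest eigenvalue and Moore–Penrose
pseudo-inverse semantics.

A design choice worth stating: the likelihood itself never inverts a GRM.
All REML computation happens on the record-space covariance
$\mathbf{V} = \sum_k \sigma^2_k \mathbf{Z}_k\mathbf{C}_k\mathbf{Z}_k' +
\sigma^2_e\mathbf{I}$, which is positive definite whenever
$\sigma^2_e > 0$ regardless of GRM rank. A single dense code path handles
the null and full models identically — with two GRM terms sharing the
animal incidence there is no common eigenbasis to rotate into, so the dense
path is also the honest cost model. It is comfortable up to a few thousand
records on one core, which covers flock-scale dairy data.

## REML algorithm

`fit_reml()` maximizes the restricted log-likelihood

$$\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|\mathbf{V}|
 + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}|
 + \mathbf{y}'\mathbf{P}\mathbf{y}\right]$$

by projected average-information (AI) iterations:

* the AI step solves the Newton-like system with the average-information
  matrix; if it leaves the feasible region or decreases $\ell_R$ it is
  halved (up to 12 times);
* if no AI step is acceptable, an expectation–maximization update
  $\sigma^2_k \leftarrow \sigma^2_k + (\sigma^4_k/q_k)
  (\mathbf{y}'\mathbf{P}\mathbf{M}_k\mathbf{P}\mathbf{y} -
  \mathrm{tr}(\mathbf{P}\mathbf{M}_k))$ is taken — guaranteed uphill,
  slower;
* components are constrained to $\ge 10^{-8}\,\mathrm{var}(y)$. A component
  sitting at that bound with an outward-pointing gradient is frozen for the
  iteration and the AI system is solved on the free components only; it
  re-enters as soon as its gradient turns positive. Without this projection
  the plain AI/EM combination oscillates for fits whose regional variance
  is truly zero — the common case in a scan — and fails to converge.
* convergence is declared when $|\Delta \ell_R| < 10^{-6}$ (default);
  non-convergence is flagged on the result, never raised, and flagged
  windows are retained in scan output.

Initialization is an equal split of $\mathrm{var}(y)$ across components;
window fits warm-start from the null estimates with $\sigma^2_v$ at 1% of
$\sigma^2_p$. Boundary-pinned components *stay in the model*; the
degrees-of-freedom consequences are handled by the mixture null below, not
by refitting a reduced model. Fixed-effect rank deficiencies (unobserved
parity or fortnight classes in small data) are resolved by dropping
dependent columns via pivoted QR, recorded on the frame.

The likelihood convention includes the constant
$-\tfrac12(n-p)\log 2\pi$ and the $\log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}|$
term without a $\log|\mathbf{X}'\mathbf{X}|$ offset; any fixed convention
cancels in the full-vs-null differences the scan uses, and the test suite
pins this one against a dense-formula oracle and the residual-only closed
form $\hat\sigma^2_e = \mathrm{RSS}/(n-p)$.

## Windows, LRT and thresholds

`make_windows()` tiles each chromosome with windows of 100 consecutive
SNPs shifted by 50, so adjacent windows overlap by half. Full windows are
laid while they fit; the remaining SNPs after the last full window form one
non-overlapping tail window, dropped when it holds fewer than 25 SNPs.
This "full windows then tail" reading is the only one under which a
sub-25-SNP exclusion can ever trigger — any scheme that truncates the last
overlapping window always leaves at least 50 SNPs.

Each window's LRT is $2(\ell_{H1} - \ell_{H0})$, clamped at zero when
numerically negative (recorded in the `clamped` column). Because
$\sigma^2_v$ is tested on the boundary of its parameter space, the null
distribution is the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; `mixture_pvalue()` returns 1 at
LRT = 0 and $\tfrac12\Pr(\chi^2_1 \ge \mathrm{LRT})$ otherwise.

`scan_thresholds()` counts $n$ half-overlapping windows as $T = n/2$
effective tests. The genome-wide threshold solves
$\tfrac12\Pr(\chi^2_1 \ge x) = \alpha/T$ under the mixture; the suggestive
threshold (one expected false positive per scan) solves
$\Pr(\chi^2_1 \ge x) = 1/T$ on the plain $\chi^2_1$ tail. This deliberately
mixed pairing is the convention that reproduces both customary published
values for an 827-window ovine scan (13.48 and 9.20, with per-test levels
$1.21\times10^{-4}$ and $2.41\times10^{-3}$); the internally consistent
all-mixture alternative is available via `consistent_mixture = TRUE` and
yields a lower suggestive threshold. Under the mixture null the plain-tail
suggestive convention also makes "one false positive per scan" exact: each
of the $n$ windows exceeds the threshold with probability
$\tfrac12\Pr(\chi^2_1 \ge x) = \tfrac12\cdot\tfrac1T = \tfrac1n$, so the
expected exceedance count per scan is 1 — a property the null-calibration
test checks empirically. Classification is strict: a window at exactly the
threshold is not significant. Thresholds are always computed from the
*realized* window count of the current scan, never hard-coded.

## Quality control conventions

`apply_genotype_qc()` filters in a fixed order: non-autosomes (sheep
autosomes `"1"`–`"26"` by default, configurable) → sample call rate →
SNP call rate → minor allele frequency → Hardy–Weinberg. Call-rate and MAF
retention are strict (`> 0.95`, `> 0.02`); HWE removal is strict
(`p < 0.001`). Frequencies and HWE are computed after sample removal, on
observed genotypes only, pooled across flocks (per-flock testing is a
defensible alternative; pooling matches the single-population design). The
HWE test is the exact conditional test — heterozygote-count enumeration at
fixed allele counts via a log-gamma closed form — not the asymptotic
$\chi^2$, matching the behaviour of the standard QC tools this order is
modelled on. QC is idempotent and its report reconciles exactly at every
stage. Phenotype QC (`filter_testday_records()`) drops lactations longer
than 300 days (by last-record DIM), lactations with fewer than 3 records,
and records missing the analysed trait, in that order; genotype and
phenotype QC are independent.

## The synthetic-data generator

No flock-scale ovine test-day dataset with genotypes is publicly
deposited, so `sim_config()`/`simulate_dataset()` generate one with
exactly the statistical structure the model assumes, plus known truth for
recovery testing:

* genotypes: biallelic SNPs on 26 autosomes (defaults: 480 ewes, ~37k
  SNPs), dosages $\mathrm{Bin}(2, p_i)$ with $p_i$ uniform on
  (0.02, 0.5], in linkage equilibrium; an optional AR(1) gamete-copula
  mode adds local correlation but is not needed — the window-level effect
  supplies all within-window signal the scan relies on;
* genetics: polygenic values from all SNPs and regional values from each
  configured QTL window, both *rescaled so the realized sample variance
  equals the target exactly*, removing one layer of Monte-Carlo noise from
  recovery tests;
* records: each flock has a monthly calendar of recording dates; an animal
  is recorded at its flock's first $n_{td}$ dates after lambing, so flock
  mates recorded the same day share an FTD level (about 180 levels arise
  for 4 flocks over 6 years at the default sizes). Lambings are 330 days
  apart across parities with 0–59 days of jitter, which makes season of
  lambing vary; DIM is date minus lambing date. Default 3–10 records per
  lactation keeps monthly recording inside the 300-day QC bound;
* variances: the default unit-phenotypic split
  (`u` 0.11, `pu` 0.07, `pw` 0.06, `h` 0.40, `e` 0.36) mirrors the
  fat-percentage pattern of flock-recorded dairy sheep, where
  flock-by-test-day dominates.

What the generator does **not** emulate: realistic linkage disequilibrium
maps, half-sib family structure and pedigree relationships beyond what the
GRM captures, selection, drift, or unbalanced flock sizes. Passing
calibration and recovery tests on these data therefore demonstrates the
estimator and test are correct *under the model's own assumptions*; they do
not certify behaviour under model misspecification in real data.

## Validation design and problem sizes

The test suite validates four statistical properties at sizes chosen for a
single CPU core (all seeds fixed):

* *likelihood correctness*: `restricted_loglik()` equals a dense-matrix
  textbook evaluation to $10^{-8}$ on random small frames and the
  residual-only closed form to $10^{-10}$;
* *recovery*: 20 replicates of 300 animals × 3,000 SNPs × ~6 records;
  mean component estimates fall within 2 empirical standard errors of the
  generative truth. Animal and SNP counts matter here: the additive and
  across-lactation permanent components share the animal incidence and are
  separated only by the GRM's off-diagonals, whose sampling noise among
  unrelated animals shrinks as $1/\sqrt{m}$, so a thin SNP panel makes the
  split weakly identified;
* *null calibration*: 50 replicate pure-null scans of ~100 windows each
  (80 animals, 2 × 2,570 SNPs); half the window LRTs sit exactly at zero,
  tail frequencies are dominated by the mixture at the 5% and 1% levels,
  and the suggestive threshold yields about one exceedance per scan;
* *localization*: a single window carrying 5% of the phenotypic variance
  (500 animals, 2 × 300 SNPs, ~3 records per ewe) is found by the top-LRT
  window — sharing at least 50 SNPs with the truth — in at least 18 of 20
  seeds.

## Known limitations

* Dense record-space likelihood: cost grows as $n^3$ in the number of
  records; tens of thousands of records need a sparse or rotated
  implementation.
* The regional scan reuses one null fit per trait; if the background model
  is misspecified, all windows inherit that misspecification.
* With `exclude_region_from_background = TRUE` the full model's background
  GRM changes per window while the null fit keeps all SNPs, so that mode is
  exploratory; the default (window SNPs present in both matrices) is the
  standard convention.
* The half-count of effective tests ($T = n/2$) is a heuristic for the
  half-overlap correlation, not an estimate of the effective number of
  independent tests.
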