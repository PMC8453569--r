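test_that("simulation is deterministic given the seed and sensitive to it", {
  cfg <- sim_config(n_animals = 30, snps_per_chromosome = c(60, 60), n_flocks = 2,
                    parities_per_animal = 2, testdays_per_lactation = c(3, 4),
                    traits = "my", seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$genotypes$map, s2$genotypes$map)
  expect_identical(s1$phenotypes, s2$phenotypes)

  cfg2 <- sim_config(n_animals = 30, snps_per_chromosome = c(60, 60), n_flocks = 2,
                     parities_per_animal = 2, testdays_per_lactation = c(3, 4),
                     traits = "my", seed = 8)
  s3 <- simulate_dataset(cfg2)
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("genotype margins follow the binomial sampling model", {
  # degenerate maf range: every SNP at p = 0.5
  cfg <- sim_config(n_animals = 400, snps_per_chromosome = 50,
                    maf_range = c(0.5, 0.5), traits = "my", seed = 3)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$dosage) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 400))
  expect_true(all(abs(freq - 0.5) < 4 * se))

  # Hardy-Weinberg heterozygosity at p = 0.3: 2pq = 0.42
  cfg <- sim_config(n_animals = 1000, snps_per_chromosome = 200,
                    maf_range = c(0.3, 0.3), traits = "my", seed = 4)
  g <- simulate_genotypes(cfg)
  het <- mean(g$dosage == 1)
  sd_het <- sqrt(0.42 * 0.58 / (1000 * 200))
  expect_lt(abs(het - 0.42), 3 * sd_het)

  # map positions strictly increase within chromosome
  bp_ok <- tapply(g$map$bp, g$map$chrom, function(b) all(diff(b) > 0))
  expect_true(all(bp_ok))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "rhmscan_config_error")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), class = "rhmscan_config_error")
  expect_error(sim_config(n_animals = 1), class = "rhmscan_config_error")
  expect_error(sim_config(parities_per_animal = 6), class = "rhmscan_config_error")
  expect_error(sim_config(testdays_per_lactation = c(0, 3)), class = "rhmscan_config_error")
  expect_error(sim_config(true_components = c(u = -1, pu = 0, pw = 0, h = 0, e = 1)),
               class = "rhmscan_config_error")
  expect_error(sim_config(snps_per_chromosome = c(100),
                          qtl_windows = list(list(chrom = 1, from = 50, to = 120, var_v = 0.1))),
               class = "rhmscan_config_error")
  expect_error(sim_config(snps_per_chromosome = c(100),
                          qtl_windows = list(list(chrom = 3, from = 1, to = 10, var_v = 0.1))),
               class = "rhmscan_config_error")
})

test_that("QTL and polygenic effects hit their target variances exactly", {
  cfg <- sim_config(n_animals = 120, snps_per_chromosome = c(200, 200),
                    qtl_windows = list(list(chrom = 1, from = 1, to = 100, var_v = 0.03),
                                       list(chrom = 2, from = 50, to = 149, var_v = 0)),
                    traits = "my", seed = 9)
  g <- simulate_genotypes(cfg)
  tr <- simulate_qtl_effects(g, cfg)
  gen <- tr$genetic$my
  expect_equal(var(gen$v[[1]]), 0.03, tolerance = 1e-12)
  expect_identical(gen$v[[2]], numeric(120))          # var 0 -> exactly zero
  expect_equal(var(gen$u), cfg$true_components[["u"]], tolerance = 1e-12)
})

test_that("regional values of disjoint windows on independent SNPs are uncorrelated", {
  cfg <- sim_config(n_animals = 1000, snps_per_chromosome = c(100, 100),
                    qtl_windows = list(list(chrom = 1, from = 1, to = 100, var_v = 0.05),
                                       list(chrom = 2, from = 1, to = 100, var_v = 0.05)),
                    traits = "my", seed = 10)
  g <- simulate_genotypes(cfg)
  tr <- simulate_qtl_effects(g, cfg)
  expect_lt(abs(cor(tr$genetic$my$v[[1]], tr$genetic$my$v[[2]])), 0.1)
})

test_that("a monomorphic QTL window raises an error naming the window", {
  dosage <- cbind(matrix(1, 30, 3), matrix(sample(0:2, 30 * 7, replace = TRUE), 30, 7))
  ds <- make_ds(dosage)
  cfg <- sim_config(n_animals = 30, snps_per_chromosome = 10,
                    qtl_windows = list(list(chrom = 1, from = 1, to = 3, var_v = 0.1)),
                    traits = "my", seed = 1)
  expect_error(simulate_qtl_effects(ds, cfg), "1:1-3", class = "rhmscan_sim_error")
})

test_that("test-day records decompose exactly as the generative model states", {
  # all variances and coefficients zero -> all records exactly zero
  cfg0 <- sim_config(n_animals = 12, snps_per_chromosome = 30, n_flocks = 2,
                     parities_per_animal = 2, testdays_per_lactation = c(2, 3),
                     true_components = c(u = 0, pu = 0, pw = 0, h = 0, e = 0),
                     fixed_effect_coefficients = zero_fixed_effects(),
                     traits = "my", seed = 5)
  s0 <- simulate_dataset(cfg0)
  expect_true(all(s0$phenotypes$my == 0))

  # only permanent + genetic structure: within an (animal, parity) cell all
  # records share u + pu + pw, so with h = e = 0 they are identical
  cfgc <- sim_config(n_animals = 12, snps_per_chromosome = 30, n_flocks = 2,
                     parities_per_animal = 2, testdays_per_lactation = c(2, 3),
                     true_components = c(u = 0.3, pu = 0.2, pw = 0.1, h = 0, e = 0),
                     fixed_effect_coefficients = zero_fixed_effects(),
                     traits = "my", seed = 5)
  sc <- simulate_dataset(cfgc)
  within_cell <- tapply(sc$phenotypes$my,
                        paste(sc$phenotypes$animal_id, sc$phenotypes$parity),
                        function(v) diff(range(v)))
  expect_true(all(within_cell < 1e-12))

  # residual-only: record variance approximates 1 (chi-square interval)
  cfge <- sim_config(n_animals = 150, snps_per_chromosome = 30, n_flocks = 2,
                     parities_per_animal = 3, testdays_per_lactation = c(4, 6),
                     true_components = c(u = 0, pu = 0, pw = 0, h = 0, e = 1),
                     fixed_effect_coefficients = zero_fixed_effects(),
                     traits = "my", seed = 6)
  se <- simulate_dataset(cfge)
  nrec <- nrow(se$phenotypes)
  ci <- nrec / stats::qchisq(c(0.9995, 0.0005), df = nrec)
  expect_gt(var(se$phenotypes$my), min(ci))
  expect_lt(var(se$phenotypes$my), max(ci))
})

test_that("record design respects the configured structure", {
  cfg <- sim_config(n_animals = 40, snps_per_chromosome = 30, n_flocks = 3,
                    parities_per_animal = 3, testdays_per_lactation = c(3, 6),
                    traits = "my", seed = 11)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  per_lact <- table(paste(ph$animal_id, ph$parity))
  expect_true(all(per_lact >= 3 & per_lact <= 6))
  expect_true(all(ph$parity <= 5))
  expect_true(all(ph$dim >= 1))
  expect_true(all(ph$season %in% 1:2))
  expect_gt(dplyr::n_distinct(ph$season), 1)
  expect_equal(dplyr::n_distinct(ph$flock), 3)
  # no duplicate (animal, date) records
  expect_equal(anyDuplicated(ph[c("animal_id", "test_date")]), 0L)
})

test_that("realized phenotypic variance is close to the component sum", {
  cfg <- sim_config(n_animals = 250, snps_per_chromosome = c(150, 150), n_flocks = 3,
                    parities_per_animal = 3, testdays_per_lactation = c(4, 8),
                    qtl_windows = list(list(chrom = 1, from = 1, to = 100, var_v = 0.05)),
                    fixed_effect_coefficients = zero_fixed_effects(),
                    traits = "my", seed = 12)
  sim <- simulate_dataset(cfg)
  total <- sum(cfg$true_components) + 0.05
  expect_lt(abs(var(sim$phenotypes$my) - total) / total, 0.15)
  # realized variance bookkeeping is finite and non-negative
  realized <- sim$truth$realized
  expect_true(all(is.finite(realized$realized_var)))
  expect_true(all(realized$realized_var >= 0))
})

test_that("fixture writing round-trips through the standard readers", {
  cfg <- sim_config(n_animals = 25, snps_per_chromosome = c(40, 30), n_flocks = 2,
                    parities_per_animal = 2, testdays_per_lactation = c(3, 4),
                    seed = 13)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$genotypes, sim$phenotypes, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(paths["fam"])), 25)
  bim <- read.table(paths["bim"])
  expect_equal(nrow(bim), 70)
  expect_true(all(tapply(bim$V4, bim$V1, function(b) all(diff(b) > 0))))
  expect_identical(order(bim$V1), seq_len(70))   # chromosome blocks in order
  g2 <- read_plink(file.path(dir, "sim"))
  expect_identical(unname(g2$dosage), unname(sim$genotypes$dosage))
  t2 <- read_testday_table(paths["testday"])
  expect_equal(nrow(t2), nrow(sim$phenotypes))
  expect_equal(t2$my, sim$phenotypes$my, tolerance = 1e-12)
})
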