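# Shared fixture builders and independent oracles.

# hand-built genotype dataset with a linear map
make_ds <- function(dosage, chrom = NULL, sample_id = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(sample_id)) sample_id <- sprintf("A%03d", seq_len(nrow(dosage)))
  genotype_dataset(dosage,
                   map = tibble::tibble(chrom = chrom,
                                        snp_id = sprintf("s%03d", seq_len(m)),
                                        bp = ave(seq_len(m), chrom, FUN = function(i) seq_along(i) * 1000L),
                                        allele_b = "B", allele_a = "A"),
                   sample_id = sample_id)
}

# independent exact-HWE oracle: Wigginton-style probability recurrence
# P(h+2)/P(h) = 4 a b / ((h+1)(h+2)) with a, b the two homozygote counts,
# a different computational route from the package's log-gamma closed form
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  prob <- numeric(length(hets))
  prob[1] <- 1
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      a <- (nA - h) / 2
      b <- (na - h) / 2
      prob[i + 1] <- prob[i] * 4 * a * b / ((h + 1) * (h + 2))
    }
  }
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# textbook dense-matrix REML evaluation, used as the likelihood oracle
brute_loglik <- function(frame, theta) {
  K1 <- length(frame$M) + 1
  V <- diag(theta[K1], frame$n)
  for (k in seq_along(frame$M)) V <- V + theta[k] * frame$M[[k]]
  Vi <- solve(V)
  X <- frame$X
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((frame$n - frame$p) * log(2 * pi) +
            determinant(V)$modulus[1] +
            determinant(XtViX)$modulus[1] +
            drop(t(frame$y) %*% P %*% frame$y))
}

# small simulated frame for likelihood tests; high MAF floor keeps every SNP
# polymorphic in small samples
small_frame <- function(seed, n_animals = 8, snps = 40, trait = "my") {
  cfg <- sim_config(n_animals = n_animals, snps_per_chromosome = snps,
                    n_flocks = 2, parities_per_animal = 2,
                    testdays_per_lactation = c(2, 2), traits = trait,
                    maf_range = c(0.35, 0.5), seed = seed)
  sim <- simulate_dataset(cfg)
  poly <- apply(sim$genotypes$dosage, 2, var) > 0
  G <- build_grm(subset_genotypes(sim$genotypes, snps = poly))
  build_model_frame(sim$phenotypes, trait, G)
}
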