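test_that("model frames encode the test-day design correctly", {
  # 3 animals x 2 parities x 2 test-days in one flock on 4 dates
  tab <- tidyr::expand_grid(animal_id = c("A1", "A2", "A3"), parity = 1:2,
                            td = 1:2) |>
    dplyr::mutate(flock = "F1",
                  test_date = as.integer((parity - 1) * 330 + td * 30),
                  lambing_date = as.integer((parity - 1) * 330),
                  litter_size = 1L, season = 1L,
                  dim = as.integer(td * 30), my = rnorm(12))
  G <- structure(list(K = diag(3) + 0.1, sample_id = c("A1", "A2", "A3"),
                      n_snps = 10, snp_id = NULL), class = "rhm_grm")
  fr <- build_model_frame(tab, "my", G)
  expect_equal(fr$terms$pw$n_levels, 6)
  expect_equal(fr$terms$pu$n_levels, 3)
  expect_equal(fr$terms$h$n_levels, 4)
  expect_equal(names(fr$terms), c("u", "pu", "pw", "h"))
  expect_equal(fr$n, 12)

  # fortnight capping: DIM 295 -> ceiling(295/14) = 22 exactly at the cap
  tab2 <- tab
  tab2$dim[1] <- 295L
  fr2 <- build_model_frame(tab2, "my", G)
  expect_true("fim22" %in% c(colnames(fr2$X), fr2$dropped_columns))

  # animals absent from the GRM are reported
  tab3 <- tab
  tab3$animal_id[1] <- "ZZ"
  expect_error(build_model_frame(tab3, "my", G), "ZZ", class = "rhmscan_model_error")
  expect_error(build_model_frame(tab, "nope", G), "nope")
})

test_that("restricted_loglik matches dense-formula brute force on random frames", {
  set.seed(31)
  for (s in 1:10) {
    fr <- small_frame(seed = 100 + s, n_animals = 6, snps = 30)
    # keep frames tiny: n <= 30 records
    expect_lte(fr$n, 30)
    theta <- c(runif(4, 0.05, 1), runif(1, 0.2, 1))
    expect_equal(restricted_loglik(fr, theta), brute_loglik(fr, theta),
                 tolerance = 1e-8)
  }
})

test_that("residual-only REML matches the closed-form solution", {
  fr <- small_frame(seed = 55, n_animals = 10, snps = 30)
  qrX <- qr(fr$X)
  rss <- sum(qr.resid(qrX, fr$y)^2)
  s2_hat <- rss / (fr$n - fr$p)
  ll_closed <- -0.5 * ((fr$n - fr$p) * (1 + log(2 * pi * s2_hat)) +
                         determinant(crossprod(fr$X))$modulus[1])
  expect_equal(restricted_loglik(fr, c(0, 0, 0, 0, s2_hat)), ll_closed,
               tolerance = 1e-10)
  # s2_hat maximizes the residual-only profile
  for (s2 in s2_hat * c(0.5, 0.9, 1.1, 2)) {
    expect_lt(restricted_loglik(fr, c(0, 0, 0, 0, s2)),
              restricted_loglik(fr, c(0, 0, 0, 0, s2_hat)))
  }
})

test_that("the restricted likelihood is invariant to record order and to shifts
           in the fixed-effect span", {
  fr <- small_frame(seed = 56, n_animals = 8, snps = 30)
  theta <- c(0.2, 0.1, 0.1, 0.3, 0.5)
  ll <- restricted_loglik(fr, theta)
  set.seed(1)
  perm <- sample(fr$n)
  fr_p <- fr
  fr_p$y <- fr$y[perm]
  fr_p$X <- fr$X[perm, , drop = FALSE]
  fr_p$M <- lapply(fr$M, function(m) m[perm, perm])
  expect_equal(restricted_loglik(fr_p, theta), ll, tolerance = 1e-9)

  fr_s <- fr
  fr_s$y <- fr$y + drop(fr$X %*% rnorm(fr$p, sd = 5))
  expect_equal(restricted_loglik(fr_s, theta), ll, tolerance = 1e-8)
})

test_that("REML recovers a residual-only truth and beats random grid points", {
  cfg <- sim_config(n_animals = 80, snps_per_chromosome = 120, n_flocks = 2,
                    parities_per_animal = 2, testdays_per_lactation = c(3, 4),
                    true_components = c(u = 0, pu = 0, pw = 0, h = 0, e = 1),
                    fixed_effect_coefficients = zero_fixed_effects(),
                    traits = "my", seed = 57)
  sim <- simulate_dataset(cfg)
  G <- build_grm(sim$genotypes)
  fr <- build_model_frame(sim$phenotypes, "my", G)
  fit <- fit_reml(fr)
  expect_true(fit$converged)
  lb <- 1e-8 * var(fr$y)
  expect_true(all(fit$components[c("u", "pu", "pw", "h")] < 0.05))
  expect_lt(abs(fit$components["e"] - 1), 3 * sqrt(2 / fit$n) * 2)
  expect_gte(fit$loglik, fit$loglik_init)

  set.seed(58)
  for (i in 1:5) {
    pt <- runif(5, lb, var(fr$y))
    expect_gte(fit$loglik, restricted_loglik(fr, pt))
  }
})

test_that("derived ratios follow their definitions with delta-method SEs", {
  fit <- fit_reml(small_frame(seed = 59, n_animals = 12, snps = 40))
  r <- derived_ratios(fit)
  th <- fit$components
  expect_equal(r$estimate[r$ratio == "h2"], unname(th["u"] / sum(th)))
  expect_equal(r$estimate[r$ratio == "r_acr"], unname((th["u"] + th["pu"]) / sum(th)))
  expect_equal(r$estimate[r$ratio == "r_wit"],
               unname((th["u"] + th["pu"] + th["pw"]) / sum(th)))
  expect_equal(r$estimate[r$ratio == "ftd2"], unname(th["h"] / sum(th)))
  # ordering constraint h2 <= r_acr <= r_wit and ratios in [0, 1]
  est <- setNames(r$estimate, r$ratio)
  expect_lte(est["h2"], est["r_acr"])
  expect_lte(est["r_acr"], est["r_wit"])
  expect_true(all(r$estimate >= 0 & r$estimate <= 1))

  td <- tidy(fit)
  expect_equal(td$term[td$type == "variance"], c("u", "pu", "pw", "h", "e"))
  expect_true(all(c("h2", "r_acr", "r_wit", "ftd2") %in% td$term[td$type == "ratio"]))
  gl <- glance(fit)
  expect_equal(gl$n, fit$n)
  expect_equal(gl$logLik, fit$loglik)
})

test_that("variance_ratios reproduces component-table arithmetic", {
  tab <- tibble::tibble(var_u = 2, var_pu = 1, var_pw = 1, var_h = 2, var_e = 4)
  r <- variance_ratios(tab)
  expect_equal(r$var_p, 10)
  expect_equal(r$h2, 0.2)
  expect_equal(r$r_acr, 0.3)
  expect_equal(r$r_wit, 0.4)
  expect_equal(r$ftd2, 0.2)
  # supplied var_p takes precedence (published-table mode)
  r2 <- variance_ratios(tibble::tibble(var_u = 1, var_pu = 1, var_pw = 1,
                                       var_h = 1, var_p = 8))
  expect_equal(r2$h2, 0.125)
  expect_error(variance_ratios(tibble::tibble(var_u = 1, var_pu = 1,
                                              var_pw = 1, var_h = 1)))
})

test_that("LRT statistics clamp at zero and validate nesting", {
  f_full <- list(loglik = -100, n = 10, p = 2,
                 term_names = c("u", "pu", "pw", "h", "v", "e"))
  f_null <- list(loglik = -105, n = 10, p = 2,
                 term_names = c("u", "pu", "pw", "h", "e"))
  class(f_full) <- class(f_null) <- "rhm_fit"
  expect_equal(as.numeric(lrt_statistic(f_full, f_null)), 10)
  f_full$loglik <- -105
  expect_equal(as.numeric(lrt_statistic(f_full, f_null)), 0)
  f_full$loglik <- -105 - 1e-9
  s <- lrt_statistic(f_full, f_null)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "clamped"))
  f_bad <- f_full
  f_bad$n <- 11
  expect_error(lrt_statistic(f_bad, f_null), class = "rhmscan_reml_error")
})

test_that("mixture p-values follow the boundary one-half chi-square rule", {
  expect_equal(mixture_pvalue(0), 1)
  expect_equal(mixture_pvalue(stats::qchisq(0.95, 1)), 0.025, tolerance = 1e-10)
  expect_equal(mixture_pvalue(13.48), 1.21e-4, tolerance = 0.01)
  expect_error(mixture_pvalue(-0.5))
})
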