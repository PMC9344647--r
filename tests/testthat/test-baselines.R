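test_that("gwas_logistic matches a hand-written IRLS oracle on a printed fixture", {
  # n = 40 fixture, fixed here in full; every genotype class holds both
  # outcomes, so the likelihood has an interior maximum.
  y <- c(0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1,
         0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1,
         1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 1, 1)
  g <- c(rep(0L, 14), rep(1L, 14), rep(2L, 12))
  age <- c(71, 76, 68, 81, 74, 79, 66, 72, 83, 70, 77, 69, 75, 80, 67,
           73, 78, 71, 74, 82, 65, 76, 72, 79, 68, 75, 81, 70, 73, 77,
           66, 74, 78, 69, 72, 80, 67, 75, 71, 76)
  res <- gwas_logistic(y, g, data.frame(age = age))
  orc <- oracle_irls(y, cbind(1, g, age))
  expect_equal(res$statistic, orc$beta[[2]], tolerance = 1e-6)
  expect_equal(res$p_raw, orc$p[[2]], tolerance = 1e-6)
  expect_true(res$converged)
  expect_equal(res$n_used, 40)
})

test_that("gwas_logistic flags complete separation instead of reporting p", {
  y <- rep(c(0, 1), each = 20)
  g <- rep(c(0, 2), each = 20)
  expect_warning(res <- gwas_logistic(y, g), "separation")
  expect_false(res$converged)
  expect_true(is.na(res$p_raw))
})

test_that("gwas_logistic is calibrated under the null", {
  set.seed(17)
  reps <- 1000
  n <- 300
  pvals <- vapply(seq_len(reps), function(i) {
    y <- rbinom(n, 1, 0.5)
    g <- rbinom(n, 2, 0.3)
    gwas_logistic(y, g)$p_raw
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("genotype coefficient is invariant to affine covariate rescaling", {
  set.seed(18)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  Z <- data.frame(age = runif(n, 60, 90), edu = runif(n, 10, 20))
  y <- rbinom(n, 1, stats::plogis(-0.5 + 0.4 * g + 0.02 * Z$age))
  a <- gwas_logistic(y, g, Z)
  Z2 <- data.frame(age = (Z$age - 70) / 10, edu = Z$edu * 3 + 5)
  b <- gwas_logistic(y, g, Z2)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-6)
})

test_that("pearson_snp_dx handles exact, orthogonal and permutation cases", {
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  expect_equal(pearson_snp_dx(y, y)$statistic, 1.0)
  g_orth <- c(0, 0, 2, 2, 0, 0, 2, 2)  # balanced, orthogonal to y
  expect_equal(pearson_snp_dx(y, g_orth)$statistic, 0.0)

  # Discrete 0/1 x 0/1/2 data put a sizeable probability atom exactly at the
  # observed r; the continuous t-based p approximates the permutation mid-p
  # (atom counted half), so that is the comparable oracle quantity.
  set.seed(19)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 2, 0.3)
  p_analytic <- pearson_snp_dx(y, g)$p_raw
  n_perm <- 20000
  r_obs <- abs(cor(y, g))
  r_perm <- vapply(seq_len(n_perm), function(i) abs(cor(y, sample(g))),
                   numeric(1))
  above <- sum(r_perm > r_obs + 1e-9)
  atom <- sum(abs(r_perm - r_obs) <= 1e-9)
  p_mid <- (above + 0.5 * atom + 1) / (n_perm + 1)
  expect_lt(abs(p_analytic - p_mid),
            3 * sqrt(max(p_mid * (1 - p_mid), 1e-6) / n_perm) + 2e-3)
})

test_that("partial correlation matches the recursive oracle and its limits", {
  set.seed(20)
  n <- 400
  z <- rnorm(n)
  g <- rbinom(n, 2, 0.3) + 0.5 * z
  y <- rbinom(n, 1, 0.5) + 0.3 * z
  res <- partial_corr_snp_dx(y, g, data.frame(z = z))
  expect_equal(res$statistic, oracle_partial_r(y, g, z), tolerance = 1e-10)

  # Empty covariate set reduces exactly to the Pearson baseline.
  res0 <- partial_corr_snp_dx(y, g)
  ref <- pearson_snp_dx(y, g)
  expect_equal(res0$statistic, ref$statistic)
  expect_equal(res0$p_raw, ref$p_raw)
  expect_equal(res0$method, "partial")

  # Covariates unrelated to both variables barely move the estimate.
  set.seed(21)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, stats::plogis(0.3 * g))
  Zn <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_lt(abs(partial_corr_snp_dx(y, g, Zn)$statistic -
                  pearson_snp_dx(y, g)$statistic), 0.05)

  # Outcome an exact linear function of covariates: degenerate.
  z <- rnorm(50)
  expect_error(partial_corr_snp_dx(2 * z + 1, rbinom(50, 2, 0.3),
                                   data.frame(z = z)),
               class = "endomap_degenerate_design")
})

test_that("baseline_associations runs all methods over a contrast", {
  coh <- simulate_cohort(null_config(71, n_subjects = 150, n_snps = 5))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  res <- baseline_associations(coh$genotypes, ct)
  expect_equal(nrow(res), 15)
  expect_setequal(unique(res$method), c("gwas", "pearson", "partial"))
  expect_equal(attr(res, "m"), 5)
  expect_true(all(res$p_corrected >= res$p_raw - 1e-15, na.rm = TRUE))
  cmp <- comparison_table(
    correlate_maps(diagnosis_effect_map(coh$qts, ct),
                   snp_effect_maps(coh$qts, coh$genotypes, ct)),
    res)
  expect_equal(nrow(cmp), 5)
  expect_true(all(c("p_corrected_mapcorr", "p_corrected_gwas",
                    "significant_partial") %in% names(cmp)))
})
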