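test_that("fit_linear_effect matches the closed-form OLS oracle", {
  y <- c(1.0, 2.1, 2.9, 4.2, 4.8, 6.1)
  x <- 0:5
  fit <- fit_linear_effect(y, x)
  orc <- oracle_ols(y, cbind(1, x))
  expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)
  expect_equal(fit$p, orc$p, tolerance = 1e-10)
  expect_equal(fit$df, orc$df)

  # 100 random small designs with covariates.
  set.seed(77)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    k <- sample(0:3, 1)
    x <- rnorm(n)
    Z <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    y <- rnorm(n)
    fit <- fit_linear_effect(y, x, Z)
    orc <- oracle_ols(y, cbind(1, x, Z))
    expect_equal(fit$beta, orc$beta, tolerance = 1e-8)
    expect_equal(fit$se, orc$se, tolerance = 1e-8)
    expect_equal(fit$p, orc$p, tolerance = 1e-8)
  }
})

test_that("exact fits hit the documented p-value floor", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_linear_effect(x, x)
  expect_equal(fit$beta, 1)
  expect_equal(fit$p, 1e-300)
  expect_equal(neglog10(1e-320), 300)
  expect_equal(neglog10(0.01), 2)
  expect_equal(neglog10(1), 0)
  expect_error(neglog10(-0.1), "\\[0, 1\\]")
  expect_error(neglog10(1.2), "\\[0, 1\\]")
})

test_that("degenerate and rank-deficient designs raise informative errors", {
  expect_error(fit_linear_effect(rnorm(10), rep(1, 10)),
               class = "endomap_degenerate_design")
  z <- rnorm(12)
  expect_error(fit_linear_effect(rnorm(12), z, data.frame(a = z)),
               class = "endomap_rank_deficient")
  expect_error(fit_linear_effect(rnorm(12), z, data.frame(a = 2 * z)),
               regexp = "a")
})

test_that("missing data are dropped pairwise and recorded in n_used", {
  set.seed(5)
  y <- rnorm(30); y[1:3] <- NA
  x <- rnorm(30); x[4] <- NA
  Z <- data.frame(age = rnorm(30)); Z$age[5] <- NA
  fit <- fit_linear_effect(y, x, Z)
  expect_equal(fit$n_used, 25)
  keep <- 6:30
  orc <- oracle_ols(y[keep], cbind(1, x[keep], Z$age[keep]))
  expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
})

test_that("predictor inference is invariant to covariate shifts (and FWL holds)", {
  set.seed(6)
  n <- 80
  x <- rbinom(n, 2, 0.3)
  Z <- data.frame(age = runif(n, 60, 90), sex = rbinom(n, 1, 0.5))
  y <- 0.3 * x + 0.02 * Z$age + rnorm(n)
  f1 <- fit_linear_effect(y, x, Z)
  Z2 <- Z; Z2$age <- Z$age + 1000
  f2 <- fit_linear_effect(y, x, Z2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)

  # Frisch-Waugh-Lovell: coefficient equals the slope of residualised y on
  # residualised x.
  W <- cbind(1, as.matrix(Z))
  ry <- stats::lm.fit(W, y)$residuals
  rx <- stats::lm.fit(W, x)$residuals
  expect_equal(f1$beta, sum(rx * ry) / sum(rx^2), tolerance = 1e-10)
})

test_that("under permutation of the predictor, p-values are uniform", {
  set.seed(8)
  n <- 500
  reps <- 1000
  x <- rbinom(n, 2, 0.3)
  pvals <- vapply(seq_len(reps), function(i) {
    fit_linear_effect(rnorm(n), sample(x))$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("diagnosis map ranks planted regions on top and handles ties", {
  # Planted affected ROIs occupy the top ranks at dx_effect = 1.0, n = 400.
  hits <- vapply(1:20, function(i) {
    coh <- simulate_cohort(sim_config(n_subjects = 400, n_rois = 20,
                                      n_snps = 2, dx_effect_size = 1.0,
                                      affected_roi_indices = 1:5,
                                      seed = 300 + i))
    ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
    dxm <- diagnosis_effect_map(coh$qts, ct)
    all(top_rois(dxm, 5)$roi_id %in% sprintf("ROI%03d", 1:5))
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # Identical QT columns give identical map entries.
  coh <- simulate_cohort(null_config(40, n_subjects = 60, n_rois = 3))
  qts <- coh$qts
  qts[[3]] <- qts[[2]]
  qts[[4]] <- qts[[2]]
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  dxm <- diagnosis_effect_map(qts, ct)
  expect_equal(length(unique(dxm$neglog10_p)), 1)
})

test_that("null diagnosis maps stay below the Bonferroni line", {
  ok <- vapply(1:20, function(i) {
    coh <- simulate_cohort(sim_config(n_subjects = 150, n_rois = 116,
                                      n_snps = 1, seed = 500 + i))
    ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
    dxm <- diagnosis_effect_map(coh$qts, ct)
    max(dxm$neglog10_p) < -log10(0.05 / 116)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("snp_effect_maps does one fit per SNP-ROI pair and respects coding symmetry", {
  coh <- simulate_cohort(null_config(51, n_subjects = 120, n_rois = 6,
                                     n_snps = 4))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  maps <- snp_effect_maps(coh$qts, coh$genotypes, ct)
  expect_equal(attr(maps, "n_fits"), 4 * 6)
  expect_equal(nrow(maps), 24)

  # Swapped allele coding: identical p, negated beta.
  g2 <- coh$genotypes
  g2$snp001 <- 2L - g2$snp001
  maps2 <- snp_effect_maps(coh$qts, g2, ct)
  a <- maps[maps$predictor_id == "snp001", ]
  b <- maps2[maps2$predictor_id == "snp001", ]
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)

  # Constant SNP is excluded with a warning, not an error.
  g3 <- coh$genotypes
  g3$snp002 <- 1L
  expect_warning(maps3 <- snp_effect_maps(coh$qts, g3, ct), "snp002")
  expect_identical(attr(maps3, "invalid_snps"), "snp002")
  expect_false("snp002" %in% maps3$predictor_id)

  # Maps are deterministic functions of their inputs.
  expect_identical(as.data.frame(maps),
                   as.data.frame(snp_effect_maps(coh$qts, coh$genotypes, ct)))
})
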