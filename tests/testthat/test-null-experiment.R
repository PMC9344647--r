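test_that("compare_to_reference counts strictly-outperformed draws", {
  res <- tibble::tibble(n_significant = c(1, 2, 3, 4))
  expect_equal(compare_to_reference(res, 3), 0.5)
  expect_equal(compare_to_reference(res, 100), 1.0)
  expect_equal(compare_to_reference(res, 0), 0.0)
  expect_equal(compare_to_reference(res, 4), 0.75)  # ties excluded
})

test_that("null experiment is seeded, deterministic and validates the pool", {
  coh <- simulate_cohort(null_config(81, n_subjects = 100, n_rois = 10,
                                     n_snps = 12))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  a <- run_null_experiment(coh$qts, coh$genotypes, ct, set_size = 6,
                           n_sets = 5, seed = 3)
  b <- run_null_experiment(coh$qts, coh$genotypes, ct, set_size = 6,
                           n_sets = 5, seed = 3)
  expect_identical(a$n_significant, b$n_significant)
  expect_error(run_null_experiment(coh$qts, coh$genotypes, ct,
                                   set_size = 20, n_sets = 2),
               "pool holds")
})

test_that("null draws produce Bonferroni-bounded significant counts", {
  coh <- simulate_cohort(sim_config(n_subjects = 150, n_rois = 30,
                                    n_snps = 80, seed = 83))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  res <- run_null_experiment(coh$qts, coh$genotypes, ct, set_size = 20,
                             n_sets = 100, seed = 4)
  # Expected significant count per set is below alpha under the Bonferroni
  # bound; assert the upper bound with Monte-Carlo slack.
  expect_lte(mean(res$n_significant),
             0.05 + 3 * sd(res$n_significant) / sqrt(nrow(res)))
})

test_that("a planted hypothesis set outranks random null sets", {
  coh <- simulate_cohort(power_config(seed = 85))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  dx <- diagnosis_effect_map(coh$qts, ct)
  hyp <- correlate_maps(dx, snp_effect_maps(coh$qts, coh$genotypes, ct))
  ref <- sum(hyp$significant)
  expect_gte(ref, 1)

  pool <- simulate_genotypes(nrow(coh$qts), mafs = rep(0.3, 80),
                             seed = 86, subject_ids = coh$qts$subject_id,
                             snp_ids = sprintf("null%03d", 1:80))
  res <- run_null_experiment(coh$qts, pool, ct, set_size = 54, n_sets = 60,
                             seed = 5, reference_count = ref)
  expect_gte(attr(res, "percentile_outperformed"), 0.95)
  g <- glance(res)
  expect_equal(g$reference_count, ref)
})

test_that("a random reference draw is exchangeable with the null draws", {
  # With the reference set itself drawn from the null pool, its tie-adjusted
  # percentile (strictly-below fraction plus half the tied fraction) has
  # expectation 1/2 under exchangeability.
  coh <- simulate_cohort(sim_config(n_subjects = 100, n_rois = 10,
                                    n_snps = 24, seed = 91))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  dx <- diagnosis_effect_map(coh$qts, ct)
  pool_ids <- setdiff(names(coh$genotypes), "subject_id")
  outer <- 200
  base <- run_null_experiment(coh$qts, coh$genotypes, ct, set_size = 6,
                              n_sets = 50, seed = 92)
  set.seed(93)
  mids <- vapply(seq_len(outer), function(i) {
    picked <- sample(pool_ids, 6)
    maps <- suppressWarnings(
      snp_effect_maps(coh$qts, coh$genotypes[c("subject_id", picked)], ct))
    ref <- sum(suppressWarnings(correlate_maps(dx, maps))$significant)
    mean(base$n_significant < ref) + 0.5 * mean(base$n_significant == ref)
  }, numeric(1))
  expect_lt(abs(mean(mids) - 0.5), 3 * sd(mids) / sqrt(outer) + 0.02)
})

test_that("reference percentile does not decrease with planted effect size", {
  # Calibrated permutation p throughout, so that null-set counts reflect the
  # nominal level rather than analytic tail error against a structured
  # diagnostic map.
  percentile_at <- function(effect, seed) {
    w <- numeric(30); w[1:10] <- 0.5 / sqrt(10)
    cfg <- sim_config(n_subjects = 300, n_rois = 30, n_snps = 10,
                      causal_snp_indices = 1:2,
                      causal_roi_indices = list(1:5, 6:10),
                      snp_effect_size = effect, dx_effect_size = 1.0,
                      affected_roi_indices = 1:10, liability_weights = w,
                      seed = seed)
    coh <- simulate_cohort(cfg)
    ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
    dx <- diagnosis_effect_map(coh$qts, ct)
    set.seed(seed)
    ref <- sum(correlate_maps(
      dx, snp_effect_maps(coh$qts, coh$genotypes, ct),
      p_method = "permutation", n_perm = 1000)$significant)
    pool <- simulate_genotypes(300, mafs = rep(0.3, 30), seed = seed + 1,
                               subject_ids = coh$qts$subject_id,
                               snp_ids = sprintf("null%03d", 1:30))
    res <- run_null_experiment(coh$qts, pool, ct, set_size = 10,
                               n_sets = 40, seed = seed + 2,
                               p_method = "permutation", n_perm = 1000)
    compare_to_reference(res, ref)
  }
  # Averaged over a few seeds per tier to damp replicate noise.
  tiers <- vapply(c(0, 0.6, 1.2), function(eff) {
    mean(vapply(1:3, function(s) percentile_at(eff, 900 + 10 * s),
                numeric(1)))
  }, numeric(1))
  expect_true(tiers[1] <= tiers[2] + 0.1 && tiers[2] <= tiers[3] + 0.1)
})
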