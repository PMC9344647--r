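# Shared cohort configurations for the simulation-based tests.

# Fully null cohort: no planted SNP or diagnosis effects.
null_config <- function(seed, n_subjects = 200, n_rois = 20, n_snps = 8) {
  sim_config(n_subjects = n_subjects, n_rois = n_rois, n_snps = n_snps,
             seed = seed)
}

# Mediation power fixture: six causal SNPs, each shifting its own 10-ROI
# block by 0.5 SD per allele; cases (liability-thresholded, diluted weights
# 0.5/sqrt(60)) get a 1.0 SD shift on the 60 causal ROIs.  The composite
# SNP -> diagnosis channel is weak while both brain maps are strong — the
# regime in which map correlation should outperform direct association.
power_config <- function(seed, n_subjects = 600) {
  w <- numeric(116)
  w[1:60] <- 0.5 / sqrt(60)
  sim_config(n_subjects = n_subjects, n_rois = 116, n_snps = 54,
             causal_snp_indices = 1:6,
             causal_roi_indices = split(1:60, rep(1:6, each = 10)),
             snp_effect_size = 0.5, dx_effect_size = 1.0,
             affected_roi_indices = 1:60, liability_weights = w,
             case_fraction = 0.5, seed = seed)
}

# One full pipeline pass: returns per-method detection flags for the
# planted SNPs plus the map-correlation result.
run_power_replicate <- function(seed, n_subjects = 600) {
  coh <- simulate_cohort(power_config(seed, n_subjects))
  ct <- define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
  dx <- diagnosis_effect_map(coh$qts, ct)
  sm <- snp_effect_maps(coh$qts, coh$genotypes, ct)
  ma <- correlate_maps(dx, sm)
  bl <- suppressWarnings(baseline_associations(coh$genotypes, ct))
  causal <- coh$truth$causal_snp_ids
  hit <- function(df) mean(causal %in% df$snp_id[df$significant])
  list(map_assoc = ma, causal = causal,
       rates = c(mapcorr = hit(ma),
                 gwas = hit(bl[bl$method == "gwas", ]),
                 pearson = hit(bl[bl$method == "pearson", ]),
                 partial = hit(bl[bl$method == "partial", ])))
}
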