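# Synthetic imaging-genetics cohorts with a planted mediation structure:
# SNPs shift regional imaging traits, a liability score built from those
# traits determines diagnosis, and (optionally) cases receive an additional
# regional shift.  Any SNP-diagnosis association therefore flows through the
# imaging channel, making the traits literal endophenotypes.

#' Configuration for a synthetic imaging-genetics cohort
#'
#' Collects and validates every knob of the generative model used by
#' [simulate_cohort()].  Effect sizes are expressed in units of the per-ROI
#' noise standard deviation (which is 1), so power is directly interpretable.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of imaging regions of interest (default 116, the AAL
#'   atlas parcel count).
#' @param n_snps Number of simulated SNPs (default 54).
#' @param maf_range Length-2 numeric, minor allele frequencies drawn uniformly
#'   from this interval; both ends in `(0, 0.5]`.
#' @param causal_snp_indices Integer indices of SNPs with planted effects on
#'   imaging traits (empty for a fully null cohort).
#' @param causal_roi_indices ROI indices affected by the causal SNPs: either a
#'   single integer vector (shared by all causal SNPs) or a list with one
#'   vector per causal SNP.
#' @param snp_effect_size Per-minor-allele shift of each causal (SNP, ROI)
#'   pair, in noise-SD units.
#' @param dx_effect_size Case-minus-control shift added to
#'   `affected_roi_indices` after diagnosis is assigned, in noise-SD units.
#'   With several case classes, class `k` of `K` receives `k/K` of the shift
#'   (severity tiers against one control group).
#' @param affected_roi_indices ROI indices receiving the diagnosis shift and,
#'   by default, carrying the liability weights.
#' @param covariate_effects Length-3 numeric: coefficients of age (years),
#'   sex (0/1) and education (years) on every ROI trait.
#' @param liability_weights Length-`n_rois` weights of the liability score, or
#'   `NULL` for the default: `1/sqrt(#affected)` on `affected_roi_indices`,
#'   zero elsewhere (zero everywhere if that set is empty).
#' @param case_fraction Fraction of subjects assigned to the case side of the
#'   liability threshold, strictly between 0 and 1.
#' @param case_classes Character vector of case labels, mildest first; cases
#'   are split into these tiers by liability rank.  Default `"AD"`.
#' @param control_label Label of the control class (default `"CN"`).
#' @param missing_genotype_rate Fraction of genotype entries masked as
#'   missing, in `[0, 1)`.
#' @param seed Integer seed driving all randomness (submodule streams are
#'   derived by fixed offsets).
#' @return A `sim_config` list, validated.
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- sim_config(n_subjects = 100, n_rois = 20, n_snps = 6, seed = 1)
#' @export
sim_config <- function(n_subjects,
                       n_rois = 116,
                       n_snps = 54,
                       maf_range = c(0.05, 0.5),
                       causal_snp_indices = integer(0),
                       causal_roi_indices = integer(0),
                       snp_effect_size = 0,
                       dx_effect_size = 0,
                       affected_roi_indices = integer(0),
                       covariate_effects = c(age = 0.02, sex = 0.1, education = -0.02),
                       liability_weights = NULL,
                       case_fraction = 0.5,
                       case_classes = "AD",
                       control_label = "CN",
                       missing_genotype_rate = 0,
                       seed = 1L) {
  .assert_scalar_number(n_subjects, "n_subjects", lower = 2)
  .assert_scalar_number(n_rois, "n_rois", lower = 3)
  .assert_scalar_number(n_snps, "n_snps", lower = 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  .assert_scalar_number(case_fraction, "case_fraction", lower = 0, upper = 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  .assert_scalar_number(missing_genotype_rate, "missing_genotype_rate",
                        lower = 0, upper = 1, strict_upper = TRUE)
  if (length(covariate_effects) != 3L || !is.numeric(covariate_effects)) {
    abort("`covariate_effects` must be 3 numbers (age, sex, education).")
  }

  causal_snp_indices <- as.integer(causal_snp_indices)
  if (length(causal_snp_indices) &&
      (min(causal_snp_indices) < 1 || max(causal_snp_indices) > n_snps)) {
    abort("`causal_snp_indices` out of bounds.")
  }
  if (!is.list(causal_roi_indices)) {
    causal_roi_indices <- rep(list(as.integer(causal_roi_indices)),
                              length(causal_snp_indices))
  }
  if (length(causal_roi_indices) != length(causal_snp_indices)) {
    abort("`causal_roi_indices` must supply one ROI set per causal SNP.")
  }
  causal_roi_indices <- lapply(causal_roi_indices, as.integer)
  for (idx in causal_roi_indices) {
    if (length(idx) && (min(idx) < 1 || max(idx) > n_rois)) {
      abort("`causal_roi_indices` out of bounds.")
    }
  }
  affected_roi_indices <- as.integer(affected_roi_indices)
  if (length(affected_roi_indices) &&
      (min(affected_roi_indices) < 1 || max(affected_roi_indices) > n_rois)) {
    abort("`affected_roi_indices` out of bounds.")
  }

  if (is.null(liability_weights)) {
    liability_weights <- numeric(n_rois)
    if (length(affected_roi_indices)) {
      liability_weights[affected_roi_indices] <-
        1 / sqrt(length(affected_roi_indices))
    }
  }
  if (length(liability_weights) != n_rois) {
    abort("`liability_weights` must have one weight per ROI.")
  }
  if (!is.character(case_classes) || !length(case_classes) ||
      anyDuplicated(c(control_label, case_classes))) {
    abort("`case_classes` must be distinct labels, distinct from the control label.")
  }

  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    causal_snp_indices = causal_snp_indices,
    causal_roi_indices = causal_roi_indices,
    snp_effect_size = as.numeric(snp_effect_size),
    dx_effect_size = as.numeric(dx_effect_size),
    affected_roi_indices = affected_roi_indices,
    covariate_effects = as.numeric(covariate_effects),
    liability_weights = as.numeric(liability_weights),
    case_fraction = as.numeric(case_fraction),
    case_classes = case_classes, control_label = control_label,
    missing_genotype_rate = as.numeric(missing_genotype_rate),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate genotypes at Hardy-Weinberg equilibrium
#'
#' Draws additive minor-allele genotype counts (0/1/2) independently per SNP
#' from Hardy-Weinberg proportions at the given minor allele frequencies, then
#' masks entries as missing at the requested rate.
#'
#' @param n_subjects Number of subjects (rows).
#' @param mafs Numeric vector of minor allele frequencies, one per SNP, each
#'   in `(0, 0.5]`.
#' @param missing_rate Fraction of entries set to `NA`, in `[0, 1)`.
#' @param seed Integer seed.
#' @param snp_ids,subject_ids Optional identifier vectors.
#' @return A tibble with a `subject_id` column and one integer column per SNP
#'   (`NA` = missing call).
#' @examples
#' g <- simulate_genotypes(20, mafs = c(0.1, 0.4), seed = 7)
#' @export
simulate_genotypes <- function(n_subjects, mafs, missing_rate = 0, seed = 1L,
                               snp_ids = NULL, subject_ids = NULL) {
  .assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  if (!is.numeric(mafs) || !length(mafs) || any(mafs <= 0 | mafs > 0.5)) {
    abort("Each minor allele frequency must lie in (0, 0.5].")
  }
  .assert_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1,
                        strict_upper = TRUE)
  n_subjects <- as.integer(n_subjects)
  n_snps <- length(mafs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(n_snps))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n_subjects))

  g <- withr::with_seed(as.integer(seed), {
    m <- vapply(mafs, function(q) {
      sample(0:2, n_subjects, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }, integer(n_subjects))
    if (missing_rate > 0) {
      m[runif(length(m)) < missing_rate] <- NA_integer_
    }
    m
  })
  dimnames(g) <- list(NULL, snp_ids)
  dplyr::bind_cols(tibble(subject_id = subject_ids), as_tibble(g))
}

#' Simulate a full imaging-genetics cohort
#'
#' Generates genotypes, covariates, regional imaging quantitative traits (QTs)
#' and diagnosis under a mediation layout: causal SNPs shift their target ROIs
#' additively, a liability score (`liability_weights . QT + N(0,1)`) is
#' thresholded at the `case_fraction` quantile to assign case status, and
#' cases then receive an extra shift on the affected ROIs.  There is no direct
#' SNP-to-diagnosis path: whatever marginal SNP-diagnosis association arises
#' is carried entirely by the imaging channel.
#'
#' Covariates are drawn as age ~ U(65, 85) years, sex ~ Bernoulli(0.5),
#' education ~ U(12, 20) years, and enter every ROI linearly through
#' `covariate_effects`.  Per-ROI noise is standard normal.  Genotype
#' missingness is applied only to the released genotype table; the planted
#' trait effects use the underlying complete genotypes (missingness models
#' failed calls, not absent biology).
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_cohort` list with elements `genotypes`, `qts`,
#'   `covariates`, `diagnosis` (tibbles keyed by `subject_id`), `truth`
#'   (planted structure) and `config`.
#' @examples
#' cfg <- sim_config(n_subjects = 120, n_rois = 10, n_snps = 4,
#'                   causal_snp_indices = 1, causal_roi_indices = 1:3,
#'                   snp_effect_size = 0.8, affected_roi_indices = 1:3,
#'                   seed = 42)
#' coh <- simulate_cohort(cfg)
#' table(coh$diagnosis$diagnosis)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  n <- config$n_subjects
  subject_ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("snp%03d", seq_len(config$n_snps))
  roi_ids <- sprintf("ROI%03d", seq_len(config$n_rois))

  mafs <- withr::with_seed(config$seed, {
    runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  })

  # Complete genotypes drive the traits; the mask is applied afterwards.
  geno_full <- simulate_genotypes(n, mafs, missing_rate = 0,
                                  seed = .split_seed(config$seed, "genotypes"),
                                  snp_ids = snp_ids, subject_ids = subject_ids)
  G <- .id_matrix(geno_full)

  covariates <- withr::with_seed(.split_seed(config$seed, "covariates"), {
    tibble(subject_id = subject_ids,
           age = round(runif(n, 65, 85), 1),
           sex = rbinom(n, 1, 0.5),
           education = round(runif(n, 12, 20)))
  })
  Zmat <- .id_matrix(covariates)

  Y <- withr::with_seed(.split_seed(config$seed, "qts"), {
    matrix(rnorm(n * config$n_rois), n, config$n_rois)
  })
  Y <- Y + Zmat %*% matrix(rep(config$covariate_effects, config$n_rois), 3)
  for (j in seq_along(config$causal_snp_indices)) {
    s <- config$causal_snp_indices[j]
    rois <- config$causal_roi_indices[[j]]
    Y[, rois] <- Y[, rois] + config$snp_effect_size * G[, s]
  }

  # Liability from the pre-shift traits; cases are the top case_fraction.
  liab <- withr::with_seed(.split_seed(config$seed, "liability"), {
    drop(Y %*% config$liability_weights) + rnorm(n)
  })
  cut <- quantile(liab, probs = 1 - config$case_fraction, type = 1)
  is_case <- liab > cut
  diagnosis <- rep(config$control_label, n)
  k_classes <- length(config$case_classes)
  if (any(is_case)) {
    tier <- ceiling(rank(liab[is_case], ties.method = "first") /
                      sum(is_case) * k_classes)
    diagnosis[is_case] <- config$case_classes[tier]
    if (length(config$affected_roi_indices) && config$dx_effect_size != 0) {
      shift <- config$dx_effect_size * tier / k_classes
      Y[is_case, config$affected_roi_indices] <-
        Y[is_case, config$affected_roi_indices] + shift
    }
  }

  genotypes <- geno_full
  if (config$missing_genotype_rate > 0) {
    Gm <- .id_matrix(genotypes)
    mask <- withr::with_seed(.split_seed(config$seed, "genotypes") + 1L, {
      matrix(runif(length(Gm)) < config$missing_genotype_rate, nrow(Gm))
    })
    Gm[mask] <- NA_real_
    genotypes <- dplyr::bind_cols(
      tibble(subject_id = subject_ids),
      as_tibble(matrix(as.integer(Gm), n, dimnames = list(NULL, snp_ids)))
    )
  }

  dimnames(Y) <- list(NULL, roi_ids)
  structure(list(
    genotypes = genotypes,
    qts = dplyr::bind_cols(tibble(subject_id = subject_ids), as_tibble(Y)),
    covariates = covariates,
    diagnosis = tibble(subject_id = subject_ids, diagnosis = diagnosis),
    truth = list(
      mafs = setNames(mafs, snp_ids),
      causal_snp_ids = snp_ids[config$causal_snp_indices],
      causal_snp_indices = config$causal_snp_indices,
      causal_roi_indices = config$causal_roi_indices,
      snp_effect_size = config$snp_effect_size,
      dx_effect_size = config$dx_effect_size,
      affected_roi_indices = config$affected_roi_indices,
      liability_weights = config$liability_weights,
      seed = config$seed
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d ROIs, %d SNPs (%d causal), seed %d\n",
    x$config$n_subjects, x$config$n_rois, x$config$n_snps,
    length(x$truth$causal_snp_indices), x$config$seed))
  print(table(x$diagnosis$diagnosis))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in plain interchange formats: genotypes both as a minimal
#' VCF (one pseudo-contig, GT field, missing as `./.`) and as an
#' additive-dosage TSV; QTs, covariates and diagnosis as TSVs keyed by
#' `subject_id`; the planted-truth record as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) abort("Not a synthetic_cohort.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genotypes_vcf = file.path(dir, "genotypes.vcf"),
    genotypes_tsv = file.path(dir, "genotypes.tsv"),
    qts = file.path(dir, "qts.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    diagnosis = file.path(dir, "diagnosis.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes_vcf(cohort$genotypes, paths[["genotypes_vcf"]])
  readr::write_tsv(cohort$genotypes, paths[["genotypes_tsv"]])
  readr::write_tsv(cohort$qts, paths[["qts"]])
  readr::write_tsv(cohort$covariates, paths[["covariates"]])
  readr::write_tsv(cohort$diagnosis, paths[["diagnosis"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a genotype table as a minimal VCF
#'
#' One record per SNP on a single pseudo-contig (positions are row numbers;
#' the package never interprets genomic coordinates).  Genotype 0/1/2 copies
#' of the ALT allele are written as `0/0`, `0/1`, `1/1`; missing as `./.`.
#'
#' @param genotypes Tibble with `subject_id` plus one 0/1/2 column per SNP.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  G <- .id_matrix(genotypes)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(G)), function(j) {
    gt <- ifelse(is.na(G[, j]), "./.", gt_code[as.character(G[, j])])
    paste(c("chrS", j, colnames(G)[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
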