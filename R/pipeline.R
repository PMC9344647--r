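# End-to-end driver: genotype QC, step-1/2 significance maps, step-3 map
# correlations, direct baselines and (optionally) the random-SNP null
# experiment, for every configured diagnostic contrast, writing TSV/JSON
# artifacts to an output directory.

#' Pipeline run configuration
#'
#' Validates and assembles the configuration consumed by [run_pipeline()].
#' Contrasts are given as a list of `list(control =, case =)` label pairs;
#' all subject alignment is by `subject_id` join.
#'
#' @param genotypes_file Genotype VCF or additive-dosage TSV.
#' @param qts_file Imaging-trait TSV (`subject_id` + ROI columns).
#' @param covariates_file Covariate TSV (`subject_id`, age, sex, education).
#' @param diagnosis_file Diagnosis TSV (`subject_id`, `diagnosis`).
#' @param contrasts List of `list(control =, case =)` pairs; at least one.
#' @param output_dir Directory for all written artifacts.
#' @param qc Run genotype QC before mapping (default TRUE, cohort-wide before
#'   any contrast subsetting).
#' @param qc_thresholds Named numeric: `call_rate`, `maf`, `hwe_p`.
#' @param alpha Significance level on Bonferroni-corrected p.
#' @param bonferroni_m Family size policy: `"per_contrast"` (default; the
#'   SNPs tested within each contrast) or a fixed number.
#' @param genotype_format Passed to [read_genotypes()].
#' @param sex_map Passed to [read_covariates()].
#' @param null_experiment Optional list with `pool_file` (background genotype
#'   file), `set_size`, `n_sets` to also run [run_null_experiment()].
#' @param seed Integer seed (null experiment draws).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genotypes_file, qts_file, covariates_file,
                       diagnosis_file, contrasts, output_dir,
                       qc = TRUE,
                       qc_thresholds = c(call_rate = 0.95, maf = 0.05,
                                         hwe_p = 1e-6),
                       alpha = 0.05, bonferroni_m = "per_contrast",
                       genotype_format = "auto",
                       sex_map = c(M = 1, F = 0, `1` = 1, `0` = 0),
                       null_experiment = NULL, seed = 1L) {
  files <- c(genotypes_file, qts_file, covariates_file, diagnosis_file)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files)) {
    abort(paste0("Input file(s) not found: ",
                 paste(missing_files, collapse = ", ")))
  }
  if (!is.list(contrasts) || !length(contrasts)) {
    abort("At least one contrast (list(control =, case =)) is required.")
  }
  for (ct in contrasts) {
    if (!all(c("control", "case") %in% names(ct))) {
      abort("Each contrast needs `control` and `case` labels.")
    }
  }
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  structure(list(
    genotypes_file = genotypes_file, qts_file = qts_file,
    covariates_file = covariates_file, diagnosis_file = diagnosis_file,
    contrasts = contrasts, output_dir = output_dir, qc = isTRUE(qc),
    qc_thresholds = qc_thresholds, alpha = alpha,
    bonferroni_m = bonferroni_m, genotype_format = genotype_format,
    sex_map = sex_map, null_experiment = null_experiment,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' File fields mirror the arguments of [run_config()]; relative input paths
#' are resolved against the config file's directory.
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs need the yaml package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  }
  if (is.data.frame(cfg$contrasts)) {
    cfg$contrasts <- purrr::transpose(as.list(cfg$contrasts))
  }
  args <- list(
    genotypes_file = resolve(cfg$genotypes_file),
    qts_file = resolve(cfg$qts_file),
    covariates_file = resolve(cfg$covariates_file),
    diagnosis_file = resolve(cfg$diagnosis_file),
    contrasts = cfg$contrasts,
    output_dir = resolve(cfg$output_dir)
  )
  for (nm in c("qc", "alpha", "bonferroni_m", "genotype_format", "seed")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  if (!is.null(cfg$qc_thresholds)) {
    args$qc_thresholds <- unlist(cfg$qc_thresholds)
  }
  if (!is.null(cfg$null_experiment)) {
    cfg$null_experiment$pool_file <- resolve(cfg$null_experiment$pool_file)
    args$null_experiment <- cfg$null_experiment
  }
  do.call(run_config, args)
}

#' Run the full endophenotype-enrichment pipeline
#'
#' Reads all inputs, optionally applies genotype QC, and for every
#' configured contrast computes the diagnostic significance map (step 1),
#' the per-SNP maps (step 2), the SNP-diagnosis map correlations (step 3)
#' and the three direct baselines, writing one TSV per artifact plus a JSON
#' summary.  Rerunning with an identical config and seed reproduces every
#' output byte for byte.
#'
#' @param config A [run_config()] (or path readable by [read_run_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the QC report and, per contrast, the
#'   effect maps, `map_assoc`, `direct_assoc` and any `null_experiment`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort("`config` must come from run_config() or read_run_config().")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  genotypes <- read_genotypes(config$genotypes_file,
                              format = config$genotype_format)
  qts <- read_qts(config$qts_file)
  covariates <- read_covariates(config$covariates_file,
                                sex_map = config$sex_map)
  diagnosis <- read_diagnosis(config$diagnosis_file)
  shared <- Reduce(intersect, list(genotypes$subject_id, qts$subject_id,
                                   covariates$subject_id,
                                   diagnosis$subject_id))
  if (!length(shared)) {
    abort("No subject ID is shared across genotype, QT, covariate and diagnosis files.")
  }
  say("Loaded %d subjects (%d with all modalities), %d SNPs, %d ROIs",
      nrow(genotypes), length(shared), ncol(genotypes) - 1, ncol(qts) - 1)

  results <- list()
  if (config$qc) {
    th <- config$qc_thresholds
    qc_out <- apply_qc(genotypes, call_rate_min = th[["call_rate"]],
                       maf_min = th[["maf"]], hwe_p_min = th[["hwe_p"]])
    write_qc_report(qc_out$report, file.path(config$output_dir, "qc_report.tsv"))
    say("QC: %d of %d SNPs pass", sum(qc_out$report$pass), nrow(qc_out$report))
    genotypes <- qc_out$genotypes
    results$qc_report <- qc_out$report
    if (ncol(genotypes) < 2) abort("No SNP survived quality control.")
  }

  summary_counts <- list()
  for (ct in config$contrasts) {
    contrast <- define_contrast(diagnosis, covariates,
                                control = ct$control, case = unlist(ct$case))
    cname <- attr(contrast, "contrast_name")
    slug <- gsub("[^A-Za-z0-9_-]+", "_", cname)
    say("Contrast %s: %d subjects (%d cases)", cname, nrow(contrast),
        sum(contrast$x))

    dx_map <- diagnosis_effect_map(qts, contrast)
    snp_maps <- snp_effect_maps(qts, genotypes, contrast)
    m <- if (identical(config$bonferroni_m, "per_contrast")) NULL else {
      as.numeric(config$bonferroni_m)
    }
    assoc <- correlate_maps(dx_map, snp_maps, alpha = config$alpha, m = m)
    direct <- baseline_associations(genotypes, contrast,
                                    alpha = config$alpha, m = attr(assoc, "m"))
    out <- file.path(config$output_dir, slug)
    dir.create(out, showWarnings = FALSE)
    write_effect_map(dx_map, file.path(out, "diagnosis_map.tsv"))
    write_effect_map(snp_maps, file.path(out, "snp_roi_table.tsv"))
    write_map_assoc(assoc, file.path(out, "map_associations.tsv"))
    readr::write_tsv(comparison_table(assoc, direct),
                     file.path(out, "method_comparison.tsv"))
    say("  step 2: %d fits; step 3: %d/%d SNPs significant",
        attr(snp_maps, "n_fits"), sum(assoc$significant), nrow(assoc))

    res <- list(contrast = contrast, dx_map = dx_map, snp_maps = snp_maps,
                map_assoc = assoc, baselines = direct)
    if (!is.null(config$null_experiment)) {
      ne <- config$null_experiment
      pool <- read_genotypes(ne$pool_file, format = config$genotype_format)
      nullexp <- run_null_experiment(
        qts, pool, contrast,
        set_size = ne$set_size %||% (ncol(genotypes) - 1),
        n_sets = ne$n_sets %||% 1000,
        seed = config$seed, alpha = config$alpha,
        reference_count = sum(assoc$significant))
      write_null_experiment(nullexp, file.path(out, "null_histogram.tsv"))
      res$null_experiment <- nullexp
      say("  null experiment: reference count %d outperforms %.2f%% of %d draws",
          sum(assoc$significant),
          100 * attr(nullexp, "percentile_outperformed"), nrow(nullexp))
    }
    results[[cname]] <- res
    summary_counts[[cname]] <- list(
      n_subjects = nrow(contrast), n_cases = sum(contrast$x),
      n_snps_tested = nrow(assoc),
      n_significant_mapcorr = sum(assoc$significant),
      n_significant_baselines = as.list(
        tapply(direct$significant, direct$method, sum)),
      null_percentile = if (!is.null(res$null_experiment)) {
        attr(res$null_experiment, "percentile_outperformed")
      }
    )
  }
  jsonlite::write_json(
    list(seed = config$seed, alpha = config$alpha,
         contrasts = summary_counts),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
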