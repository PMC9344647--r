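# Genotype quality control: per-SNP call rate, minor allele frequency and the
# exact conditional Hardy-Weinberg test, with the conventional strict
# thresholds call rate > 95%, MAF > 5%, HWE p > 1e-6.

#' Genotype call rate
#'
#' Fraction of non-missing genotype calls in a SNP column.
#'
#' @param genotype_column Vector of 0/1/2 genotypes with `NA` for missing.
#' @return Fraction in `[0, 1]`.
#' @examples
#' call_rate(c(0, 1, 2, NA))
#' @export
call_rate <- function(genotype_column) {
  if (!length(genotype_column)) abort("Empty genotype column.")
  mean(!is.na(genotype_column))
}

#' Minor allele frequency
#'
#' Allele frequency `f` of the counted allele among non-missing subjects,
#' folded to `min(f, 1 - f)`.  Invariant under swapping the allele coding
#' (`g` to `2 - g`).
#'
#' @inheritParams call_rate
#' @return Frequency in `[0, 0.5]`.
#' @examples
#' minor_allele_frequency(c(2, 2, 1, 0))  # 3/8
#' @export
minor_allele_frequency <- function(genotype_column) {
  g <- genotype_column[!is.na(genotype_column)]
  if (!length(g)) abort("All genotypes missing; MAF undefined.")
  if (any(!g %in% 0:2)) abort("Genotypes must be 0, 1 or 2.")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

# Exact conditional distribution of the heterozygote count given the minor
# allele count n_a and sample size n_total:
#   P(n_ab) = C(n; n_aa, n_ab, n_bb) 2^n_ab / C(2n, n_a),
# over n_ab with the parity of n_a.  Computed in log space via lgamma and
# renormalised, so it is stable up to thousands of alleles.
.hwe_het_distribution <- function(n_a, n_total) {
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n_total - n_a), by = 2L)
  n_aa <- (n_a - hets) / 2
  n_bb <- n_total - n_aa - hets
  logp <- lgamma(n_total + 1) - lgamma(n_aa + 1) - lgamma(hets + 1) -
    lgamma(n_bb + 1) + hets * log(2) -
    (lgamma(2 * n_total + 1) - lgamma(n_a + 1) - lgamma(2 * n_total - n_a + 1))
  p <- exp(logp - max(logp))
  list(hets = hets, prob = p / sum(p))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions from the genotype
#' counts of a biallelic SNP.  Conditional on the observed allele counts, the
#' heterozygote count has a known null distribution; the p-value is the total
#' probability of all heterozygote configurations no more probable than the
#' observed one (the standard two-sided tail definition, without the mid-p
#' adjustment).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote); any labelling works since the test folds to the minor
#'   allele.
#' @return p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 0)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Genotype counts must be non-negative integers.")
  }
  n_total <- sum(counts)
  if (n_total == 0) abort("At least one genotype is required.")
  n_a <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  d <- .hwe_het_distribution(n_a, n_total)
  p_obs <- d$prob[match(n_Aa, d$hets)]
  min(1, sum(d$prob[d$prob <= p_obs + 1e-12 * p_obs]))
}

#' Apply genotype quality control
#'
#' Screens every SNP column on three criteria — call rate, minor allele
#' frequency and the exact Hardy-Weinberg test — and drops SNPs failing any
#' of them.  Pass requires strict inequality against each threshold.  The
#' subject set is never altered.
#'
#' @param genotypes Tibble with `subject_id` plus one 0/1/2 column per SNP.
#' @param call_rate_min,maf_min,hwe_p_min Strict lower thresholds (defaults
#'   0.95, 0.05, 1e-6).
#' @return A list with `genotypes` (surviving columns) and `report`, a
#'   `qc_report` tibble with one row per input SNP: `snp_id`, `call_rate`,
#'   `maf`, `hwe_p`, `pass`; thresholds are kept as attributes.
#' @examples
#' g <- simulate_genotypes(200, mafs = c(0.3, 0.02), seed = 1)
#' apply_qc(g)$report
#' @export
apply_qc <- function(genotypes, call_rate_min = 0.95, maf_min = 0.05,
                     hwe_p_min = 1e-6) {
  G <- .id_matrix(genotypes)
  report <- purrr::map_dfr(colnames(G), function(s) {
    g <- G[, s]
    cr <- call_rate(g)
    if (all(is.na(g))) {
      return(tibble(snp_id = s, call_rate = cr, maf = NA_real_,
                    hwe_p = NA_real_, pass = FALSE))
    }
    gg <- g[!is.na(g)]
    tibble(
      snp_id = s, call_rate = cr,
      maf = minor_allele_frequency(g),
      hwe_p = hwe_exact_test(sum(gg == 0), sum(gg == 1), sum(gg == 2)),
      pass = NA
    )
  })
  report$pass <- !is.na(report$maf) &
    report$call_rate > call_rate_min &
    report$maf > maf_min &
    report$hwe_p > hwe_p_min
  attr(report, "thresholds") <- c(call_rate = call_rate_min, maf = maf_min,
                                  hwe_p = hwe_p_min)
  class(report) <- c("qc_report", class(report))

  keep <- report$snp_id[report$pass]
  if (!length(keep)) {
    warn("No SNP passed quality control; returning an empty genotype table.")
  }
  list(
    genotypes = genotypes[, c("subject_id", keep), drop = FALSE],
    report = report
  )
}

#' @export
print.qc_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "<qc_report> %d SNPs, %d pass (call rate > %g, MAF > %g, HWE p > %g)\n",
    nrow(x), sum(x$pass), th[["call_rate"]], th[["maf"]], th[["hwe_p"]]))
  NextMethod()
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
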