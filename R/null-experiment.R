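# Resampling experiment: run the full map-correlation pipeline on many
# randomly drawn SNP sets from a background pool and compare the distribution
# of significant-SNP counts with the count obtained from a designated
# hypothesis set (e.g. known susceptibility loci).

#' Random-SNP-set null experiment
#'
#' Repeatedly draws `set_size` SNPs without replacement from a background
#' genotype pool, runs steps 2-3 of the pipeline (per-SNP effect maps, map
#' correlation with the fixed diagnostic map, Bonferroni over the set) on
#' each draw, and records the number of significant SNPs.  The resulting
#' count distribution is the reference against which a hypothesis SNP set's
#' count is ranked.
#'
#' @param qts Tibble with `subject_id` plus one column per ROI.
#' @param genotype_pool Tibble with `subject_id` plus one 0/1/2 column per
#'   background SNP; must hold at least `set_size` SNPs.
#' @param contrast A [define_contrast()] object.
#' @param set_size SNPs per draw (default 54).
#' @param n_sets Number of draws (default 1000; raise to 10000 for a
#'   publication-grade histogram).
#' @param seed Integer seed; draws are reproducible and mutually independent.
#' @param alpha,m,p_method,n_perm Passed to [correlate_maps()]; `m` defaults
#'   to the number of valid maps within each draw.
#' @param reference_count Optional significant-SNP count of the hypothesis
#'   set, ranked against the draws (see [compare_to_reference()]).
#' @return A `null_experiment` object: tibble of per-draw `counts` plus
#'   attributes (`set_size`, `seed`, `reference_count`,
#'   `percentile_outperformed`).
#' @export
run_null_experiment <- function(qts, genotype_pool, contrast, set_size = 54,
                                n_sets = 1000, seed = 1L, alpha = 0.05,
                                m = NULL, p_method = "analytic",
                                n_perm = 1000L, reference_count = NULL) {
  .assert_scalar_number(n_sets, "n_sets", lower = 1)
  .assert_scalar_number(set_size, "set_size", lower = 1)
  pool_ids <- setdiff(names(genotype_pool), "subject_id")
  if (length(pool_ids) < set_size) {
    abort(sprintf("Genotype pool holds %d SNPs; %d needed per draw.",
                  length(pool_ids), set_size))
  }
  dx_map <- diagnosis_effect_map(qts, contrast)
  counts <- withr::with_seed(.split_seed(seed, "nullsets"), {
    vapply(seq_len(n_sets), function(i) {
      picked <- sample(pool_ids, set_size)
      maps <- suppressWarnings(
        snp_effect_maps(qts, genotype_pool[c("subject_id", picked)], contrast))
      if (!nrow(maps)) return(0L)
      res <- suppressWarnings(correlate_maps(dx_map, maps, alpha = alpha,
                                             m = m, p_method = p_method,
                                             n_perm = n_perm))
      sum(res$significant)
    }, integer(1))
  })
  out <- structure(
    tibble(set = seq_len(as.integer(n_sets)), n_significant = counts),
    class = c("null_experiment", "tbl_df", "tbl", "data.frame"),
    set_size = as.integer(set_size), seed = as.integer(seed),
    alpha = alpha, contrast = attr(dx_map, "contrast"),
    reference_count = reference_count,
    percentile_outperformed = NA_real_)
  if (!is.null(reference_count)) {
    attr(out, "percentile_outperformed") <-
      compare_to_reference(out, reference_count)
  }
  out
}

#' Rank a reference count against the null draws
#'
#' Fraction of resampled SNP sets whose significant count is strictly below
#' the reference count (ties do not count as outperformed).
#'
#' @param result A `null_experiment` object (or anything with an
#'   `n_significant` column).
#' @param reference_count Significant-SNP count of the hypothesis set.
#' @return Fraction in `[0, 1]`.
#' @examples
#' compare_to_reference(tibble::tibble(n_significant = c(1, 2, 3, 4)), 3)
#' @export
compare_to_reference <- function(result, reference_count) {
  counts <- result$n_significant
  if (!length(counts)) abort("No resampled counts to compare against.")
  mean(counts < reference_count)
}

#' @export
print.null_experiment <- function(x, ...) {
  cat(sprintf(
    "<null_experiment> %d draws of %d SNPs (contrast %s, alpha %g), mean count %.3f\n",
    nrow(x), attr(x, "set_size"), attr(x, "contrast"), attr(x, "alpha"),
    mean(x$n_significant)))
  ref <- attr(x, "reference_count")
  if (!is.null(ref)) {
    cat(sprintf("  reference count %d outperforms %.2f%% of draws\n",
                ref, 100 * attr(x, "percentile_outperformed")))
  }
  invisible(x)
}

#' @rdname run_null_experiment
#' @param x A `null_experiment` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.null_experiment <- function(x, ...) {
  tibble(n_sets = nrow(x), set_size = attr(x, "set_size"),
         mean_count = mean(x$n_significant),
         max_count = max(x$n_significant),
         reference_count = attr(x, "reference_count") %||% NA_integer_,
         percentile_outperformed = attr(x, "percentile_outperformed"))
}

#' Histogram of null-experiment counts
#'
#' Distribution of significant-SNP counts over the random draws, with the
#' hypothesis set's count marked as a dashed line when available.
#'
#' @param object A `null_experiment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.null_experiment <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(x = "Significant SNPs per random set", y = "Draws",
                  title = paste0("Random SNP-set null distribution (",
                                 attr(object, "contrast"), ")")) +
    ggplot2::theme_minimal()
  ref <- attr(object, "reference_count")
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_vline(xintercept = ref, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Write null-experiment histogram data as TSV
#'
#' @param result A `null_experiment` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_null_experiment <- function(result, path) {
  tab <- as_tibble(result) |> dplyr::count(.data$n_significant, name = "frequency")
  readr::write_tsv(tab, path)
  invisible(path)
}
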