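# Step 3: score each SNP by the Pearson correlation between its
# genetic-effect significance map and the diagnostic-effect map across ROIs,
# then Bonferroni-correct over the SNP family within the contrast.

#' Pearson correlation of two brain maps
#'
#' Sample Pearson correlation with the analytic two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors (`n >= 3`), both non-constant.
#' @return List with `r` and `p_raw`.
#' @examples
#' pearson_r(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("Maps must have equal length.")
  n <- length(a)
  if (n < 3) abort("At least 3 paired values are required.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Degenerate map: constant vector has no defined correlation.",
          class = "endomap_degenerate_map")
  }
  r <- cor(a, b)
  if (abs(r) >= 1) {
    p <- .P_FLOOR
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * pt(-abs(tval), n - 2), .P_FLOOR)
  }
  list(r = r, p_raw = p)
}

# Permutation p for a map correlation: ROI labels of one map are permuted,
# two-sided on |r|.  Provided because ROI maps are spatially correlated and
# the analytic t-based p assumes independent pairs.  Chunked matrix algebra
# keeps 1e5 draws cheap.
.permutation_p <- function(a, b, n_perm, chunk = 5000L) {
  n <- length(a)
  az <- as.vector(scale(a))
  bz <- as.vector(scale(b))
  r_obs <- abs(sum(az * bz) / (n - 1))
  hits <- 0L
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    P <- vapply(seq_len(k), function(i) bz[sample.int(n)], numeric(n))
    r_perm <- abs(drop(az %*% P) / (n - 1))
    hits <- hits + sum(r_perm >= r_obs - 1e-12)
    done <- done + k
  }
  (hits + 1) / (n_perm + 1)
}

#' Correlate SNP maps with the diagnostic map (step 3)
#'
#' Scores every SNP by the Pearson correlation between its significance map
#' and the diagnostic significance map over the shared, identically ordered
#' ROI vector, then applies Bonferroni correction over the SNP family and
#' flags SNPs with corrected p below `alpha`.  Constant (degenerate) maps are
#' excluded and listed.  ROI order is verified, never silently re-indexed.
#'
#' @param dx_map `effect_map` from [diagnosis_effect_map()].
#' @param snp_maps `effect_map` from [snp_effect_maps()] (same contrast, same
#'   ROI order).
#' @param alpha Significance level on the corrected p (default 0.05).
#' @param m Bonferroni family size; default the number of valid SNP maps in
#'   this contrast (each contrast is its own family).
#' @param p_method `"analytic"` (t-based, default) or `"permutation"`
#'   (ROI-label permutation; see `n_perm`), the latter offered because ROI
#'   maps are spatially correlated.
#' @param n_perm Permutation count when `p_method = "permutation"`.
#' @return A `map_assoc` tibble sorted by corrected p: `snp_id`, `contrast`,
#'   `r`, `p_raw`, `p_corrected`, `n_rois_used`, `significant`.  Excluded
#'   SNPs are in the `excluded_snps` attribute.
#' @export
correlate_maps <- function(dx_map, snp_maps, alpha = 0.05, m = NULL,
                           p_method = c("analytic", "permutation"),
                           n_perm = 10000L) {
  p_method <- match.arg(p_method)
  roi_ids <- attr(dx_map, "roi_ids")
  if (!identical(roi_ids, attr(snp_maps, "roi_ids"))) {
    abort("ROI order differs between the diagnostic and SNP maps; refusing to re-index.")
  }
  dx <- as_tibble(dx_map)
  if (!identical(dx$roi_id, roi_ids)) abort("Diagnostic map rows out of order.")
  dx_vec <- dx$neglog10_p
  if (sd(dx_vec) == 0) abort("Diagnostic map is constant; correlation undefined.")

  by_snp <- as_tibble(snp_maps) |> split(~predictor_id)
  snp_ids <- names(by_snp)
  for (s in snp_ids) {
    if (!identical(by_snp[[s]]$roi_id, roi_ids)) {
      abort(sprintf("SNP map %s has mismatched ROI order.", s))
    }
  }
  M <- vapply(by_snp, function(mp) mp$neglog10_p, numeric(length(roi_ids)))
  degenerate <- apply(M, 2, sd) == 0
  excluded <- snp_ids[degenerate]
  if (all(degenerate)) abort("No valid SNP map to correlate.")
  if (length(excluded)) {
    warn(paste0("Excluded degenerate (constant) SNP map(s): ",
                paste(excluded, collapse = ", ")))
  }
  M <- M[, !degenerate, drop = FALSE]

  stats <- purrr::map(seq_len(ncol(M)), function(j) pearson_r(dx_vec, M[, j]))
  p_raw <- purrr::map_dbl(stats, "p_raw")
  if (p_method == "permutation") {
    # One shared set of ROI permutations of the diagnostic map, correlated
    # against every SNP map by matrix product; two-sided on |r|.
    n_rois <- length(roi_ids)
    dxz <- as.vector(scale(dx_vec))
    Mz <- scale(M)
    r_obs <- abs(drop(crossprod(Mz, dxz)) / (n_rois - 1))
    perm <- vapply(seq_len(n_perm), function(i) dxz[sample.int(n_rois)],
                   numeric(n_rois))
    r_perm <- abs(crossprod(Mz, perm) / (n_rois - 1))
    hits <- rowSums(r_perm >= r_obs - 1e-12)
    p_raw <- (hits + 1) / (n_perm + 1)
  }
  out <- tibble(snp_id = snp_ids[!degenerate],
                contrast = attr(dx_map, "contrast"),
                r = purrr::map_dbl(stats, "r"), p_raw = p_raw,
                n_rois_used = length(roi_ids))
  if (is.null(m)) m <- nrow(out)
  out <- out |>
    dplyr::mutate(p_corrected = bonferroni(.data$p_raw, m),
                  significant = .data$p_corrected < alpha,
                  .after = "p_raw") |>
    dplyr::arrange(.data$p_corrected, .data$p_raw)
  structure(out, class = c("map_assoc", class(out)),
            alpha = alpha, m = m, excluded_snps = excluded,
            contrast = attr(dx_map, "contrast"), p_method = p_method)
}

#' @export
print.map_assoc <- function(x, ...) {
  cat(sprintf(
    "<map_assoc> contrast %s: %d SNPs, %d significant (Bonferroni m = %d, alpha = %g)\n",
    attr(x, "contrast"), nrow(x), sum(x$significant), attr(x, "m"),
    attr(x, "alpha")))
  NextMethod()
}

#' @rdname correlate_maps
#' @param x A `map_assoc` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.map_assoc <- function(x, ...) {
  as_tibble(x)
}

#' @rdname correlate_maps
#' @exportS3Method generics::glance
glance.map_assoc <- function(x, ...) {
  tibble(contrast = attr(x, "contrast"),
         n_snps = nrow(x),
         n_significant = sum(x$significant),
         n_excluded = length(attr(x, "excluded_snps")),
         m = attr(x, "m"),
         alpha = attr(x, "alpha"))
}

#' Map-correlation results as a ranked bar plot
#'
#' @param object A `map_assoc` object.
#' @param ... Unused.
#' @return A ggplot object: SNPs ranked by corrected significance, bar height
#'   `-log10(p_corrected)`, filled by the sign of the map correlation.
#' @exportS3Method ggplot2::autoplot
autoplot.map_assoc <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(snp_id = factor(.data$snp_id, levels = rev(.data$snp_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_id,
                                   y = neglog10(.data$p_corrected),
                                   fill = .data$r > 0)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac"),
                               name = "r > 0") +
    ggplot2::labs(x = NULL, y = expression(-log[10]("corrected p")),
                  title = paste0("SNP-diagnosis map correlations (",
                                 attr(object, "contrast"), ")")) +
    ggplot2::theme_minimal()
}

#' Write map-correlation results as TSV
#'
#' @param assoc A `map_assoc` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_map_assoc <- function(assoc, path) {
  readr::write_tsv(as_tibble(assoc), path)
  invisible(path)
}
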