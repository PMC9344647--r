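# Comparator analyses that test each SNP against diagnosis directly:
# covariate-adjusted logistic GWAS (Wald test on the additive genotype
# coefficient), Pearson correlation, and covariate-residualised partial
# correlation.  These form the benchmark against which the map-correlation
# pipeline's endophenotype enrichment is judged.

.direct_row <- function(snp_id, contrast, method, statistic, p_raw,
                        converged = TRUE, n_used = NA_integer_) {
  tibble(snp_id = snp_id, contrast = contrast, method = method,
         statistic = statistic, p_raw = p_raw, converged = converged,
         n_used = n_used)
}

#' Covariate-adjusted logistic GWAS test of one SNP
#'
#' Logistic regression of case status on the additive genotype plus
#' covariates and an intercept, fitted by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 100 iterations), with the
#' two-sided Wald test on the genotype coefficient.  Complete separation is
#' flagged: the result is marked non-converged and the p-value reported as
#' missing rather than a spuriously tiny number.
#'
#' @param diagnosis 0/1 numeric vector (1 = case).
#' @param g Additive genotype vector (0/1/2, `NA` allowed).
#' @param Z Optional covariate data frame.
#' @param snp_id,contrast Labels carried into the result.
#' @return One-row tibble: `snp_id`, `contrast`, `method = "gwas"`,
#'   `statistic` (log-odds per allele), `p_raw`, `converged`, `n_used`.
#' @export
gwas_logistic <- function(diagnosis, g, Z = NULL, snp_id = "snp",
                          contrast = "contrast") {
  keep <- !is.na(diagnosis) & !is.na(g)
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)
    keep <- keep & complete.cases(Z)
  }
  y <- as.numeric(diagnosis[keep])
  gv <- as.numeric(g[keep])
  if (length(unique(y)) < 2) abort("Both diagnostic classes are required.")
  if (sd(gv) == 0) {
    abort("Degenerate design: genotype constant in the contrast subset.",
          class = "endomap_degenerate_design")
  }
  dat <- data.frame(y = y, g = gv)
  if (!is.null(Z)) dat <- cbind(dat, Z[keep, , drop = FALSE])
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  beta <- sm["g", "Estimate"]
  separated <- !fit$converged || abs(beta) > 15 || sm["g", "Std. Error"] > 100
  if (separated) {
    warn(sprintf(
      "SNP %s: complete or quasi-complete separation; coefficient diverges, p reported as missing.",
      snp_id))
    return(.direct_row(snp_id, contrast, "gwas", beta, NA_real_,
                       converged = FALSE, n_used = length(y)))
  }
  .direct_row(snp_id, contrast, "gwas", beta,
              max(sm["g", "Pr(>|z|)"], .P_FLOOR), n_used = length(y))
}

#' Pearson correlation of one SNP with diagnosis
#'
#' Treats the 0/1 diagnosis as numeric and reports the sample correlation
#' with the additive genotype, with the two-sided t-based p on `n - 2`
#' degrees of freedom.
#'
#' @inheritParams gwas_logistic
#' @return One-row tibble (`method = "pearson"`, `statistic` = r).
#' @export
pearson_snp_dx <- function(diagnosis, g, snp_id = "snp", contrast = "contrast") {
  keep <- !is.na(diagnosis) & !is.na(g)
  pr <- pearson_r(as.numeric(diagnosis[keep]), as.numeric(g[keep]))
  .direct_row(snp_id, contrast, "pearson", pr$r, pr$p_raw,
              n_used = sum(keep))
}

#' Partial correlation of one SNP with diagnosis given covariates
#'
#' Correlation between the residuals of diagnosis-on-covariates and
#' genotype-on-covariates OLS fits (both with intercepts); the two-sided
#' p-value uses `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` for `k`
#' covariates.  With an empty covariate set this reduces exactly to
#' [pearson_snp_dx()].
#'
#' @inheritParams gwas_logistic
#' @return One-row tibble (`method = "partial"`, `statistic` = partial r).
#' @export
partial_corr_snp_dx <- function(diagnosis, g, Z = NULL, snp_id = "snp",
                                contrast = "contrast") {
  keep <- !is.na(diagnosis) & !is.na(g)
  if (is.null(Z) || NCOL(Z) == 0) {
    out <- pearson_snp_dx(diagnosis[keep], g[keep], snp_id, contrast)
    out$method <- "partial"
    return(out)
  }
  Z <- as.data.frame(Z)
  keep <- keep & complete.cases(Z)
  y <- as.numeric(diagnosis[keep])
  gv <- as.numeric(g[keep])
  Zm <- cbind(`(Intercept)` = 1, as.matrix(Z[keep, , drop = FALSE]))
  storage.mode(Zm) <- "double"
  qrZ <- qr(Zm)
  if (qrZ$rank < ncol(Zm)) {
    bad <- colnames(Zm)[qrZ$pivot[seq.int(qrZ$rank + 1L, ncol(Zm))]]
    abort(paste0("Rank-deficient covariates: ", paste(bad, collapse = ", ")))
  }
  ry <- qr.resid(qrZ, y)
  rg <- qr.resid(qrZ, gv)
  if (sd(ry) < 1e-12 * max(1, sd(y)) || sd(rg) < 1e-12 * max(1, sd(gv))) {
    abort("Degenerate residuals: a variable is an exact linear function of the covariates.",
          class = "endomap_degenerate_design")
  }
  r <- cor(ry, rg)
  df <- length(y) - 2 - (ncol(Zm) - 1)
  if (df < 1) abort("Too few subjects for partial correlation.")
  p <- if (abs(r) >= 1) .P_FLOOR else {
    max(2 * pt(-abs(r * sqrt(df / (1 - r^2))), df), .P_FLOOR)
  }
  .direct_row(snp_id, contrast, "partial", r, p, n_used = length(y))
}

#' Run all direct SNP-diagnosis baselines over a contrast
#'
#' Applies the covariate-adjusted logistic GWAS, Pearson correlation and
#' partial correlation to every SNP of a genotype table within one
#' diagnostic contrast, Bonferroni-correcting each method over the same SNP
#' family used by [correlate_maps()] so the comparison is fair.
#'
#' @param genotypes Tibble with `subject_id` plus one 0/1/2 column per SNP.
#' @param contrast A [define_contrast()] object.
#' @param alpha Significance level on corrected p.
#' @param m Bonferroni family size; default the number of testable SNPs.
#' @param methods Subset of `c("gwas", "pearson", "partial")`.
#' @return A `direct_assoc` tibble: one row per SNP x method with
#'   `statistic`, `p_raw`, `p_corrected`, `significant`.
#' @export
baseline_associations <- function(genotypes, contrast, alpha = 0.05, m = NULL,
                                  methods = c("gwas", "pearson", "partial")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!inherits(contrast, "contrast")) {
    abort("`contrast` must come from define_contrast().")
  }
  idx <- match(contrast$subject_id, genotypes$subject_id)
  if (anyNA(idx)) {
    abort("Some contrast subjects are missing from the genotype table.")
  }
  G <- .id_matrix(genotypes)[idx, , drop = FALSE]
  Z <- as.data.frame(contrast)[, setdiff(names(contrast), c("subject_id", "x")),
                               drop = FALSE]
  cname <- attr(contrast, "contrast_name")

  testable <- colnames(G)[apply(G, 2, function(g) {
    gg <- g[!is.na(g)]
    length(gg) > 3 && sd(gg) > 0
  })]
  if (is.null(m)) m <- length(testable)
  rows <- purrr::map(testable, function(s) {
    g <- G[, s]
    dplyr::bind_rows(
      if ("gwas" %in% methods)
        gwas_logistic(contrast$x, g, Z, snp_id = s, contrast = cname),
      if ("pearson" %in% methods)
        pearson_snp_dx(contrast$x, g, snp_id = s, contrast = cname),
      if ("partial" %in% methods)
        partial_corr_snp_dx(contrast$x, g, Z, snp_id = s, contrast = cname)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_corrected = ifelse(is.na(.data$p_raw), NA_real_,
                                       bonferroni(pmax(.data$p_raw, .P_FLOOR), m)),
                  significant = !is.na(.data$p_corrected) &
                    .data$p_corrected < alpha) |>
    dplyr::arrange(.data$method, .data$p_corrected)
  structure(out, class = c("direct_assoc", class(out)),
            alpha = alpha, m = m, contrast = cname)
}

#' @export
print.direct_assoc <- function(x, ...) {
  counts <- tapply(x$significant, x$method, sum)
  cat(sprintf("<direct_assoc> contrast %s (m = %d, alpha = %g): %s\n",
              attr(x, "contrast"), attr(x, "m"), attr(x, "alpha"),
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  NextMethod()
}

#' Combined method-comparison table
#'
#' Joins the map-correlation results with the direct baselines into one wide
#' table per SNP — the machine analogue of a method-comparison table —
#' reporting each method's corrected significance.
#'
#' @param map_assoc A `map_assoc` from [correlate_maps()].
#' @param direct A `direct_assoc` from [baseline_associations()].
#' @return A tibble, one row per SNP, with per-method `-log10` corrected
#'   p-values and significance flags.
#' @export
comparison_table <- function(map_assoc, direct) {
  wide <- as_tibble(direct) |>
    dplyr::select("snp_id", "method", "p_corrected", "significant") |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("p_corrected", "significant"))
  as_tibble(map_assoc) |>
    dplyr::select("snp_id", "contrast", "r",
                  p_corrected_mapcorr = "p_corrected",
                  significant_mapcorr = "significant") |>
    dplyr::left_join(wide, by = "snp_id")
}
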