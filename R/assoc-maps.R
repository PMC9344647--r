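# Steps 1-2 of the pipeline: ordinary least squares of each regional imaging
# trait on diagnosis (step 1) or on each SNP's additive genotype (step 2),
# adjusting for covariates, summarised as brain-wide significance maps of
# -log10(p) for the predictor coefficient.
#
# All models share a design per predictor, so each map is fitted with one QR
# decomposition applied to every ROI column at once; fit_linear_effect() is
# the single-trait surface over the same code path.

# Build [intercept | predictor | covariates], validate rank, and report which
# columns are collinear when it fails.
.design_matrix <- function(predictor, Z) {
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(Z) && NCOL(Z) > 0) {
    Zm <- as.matrix(Z)
    storage.mode(Zm) <- "double"
    if (is.null(colnames(Zm))) colnames(Zm) <- paste0("z", seq_len(ncol(Zm)))
    X <- cbind(X, Zm)
  }
  X
}

.check_design <- function(X) {
  if (sd(X[, "predictor"]) == 0) {
    abort("Degenerate design: the predictor is constant on the used subjects.",
          class = "endomap_degenerate_design")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "endomap_rank_deficient")
  }
  qrX
}

# OLS of every column of Y on X = [1, predictor, Z] via one QR.  Returns the
# predictor row of the coefficient table with exact-t two-sided p-values.
.fit_multi <- function(Y, predictor, Z = NULL) {
  X <- .design_matrix(predictor, Z)
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 1) abort("Too few subjects for the design (df < 1).")
  qrX <- .check_design(X)
  coefs <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  sigma2 <- colSums(resid^2) / df
  # (X'X)^{-1} from R of the QR; no pivoting occurred (full rank checked).
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * XtXinv[2, 2], 0))
  beta <- coefs[2, ]
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- pmax(2 * pt(-abs(tval), df), .P_FLOOR)
  list(beta = unname(beta), se = unname(se), t = unname(tval), p = unname(p),
       n_used = n, df = df, gamma = coefs[-2, , drop = FALSE])
}

#' Covariate-adjusted linear association of one trait with one predictor
#'
#' Fits `y = beta * predictor + Gamma * Z + intercept + error` by ordinary
#' least squares and tests `beta != 0` with the exact two-sided t-test on
#' `n_used - k - 2` degrees of freedom (k covariates).  Subjects with a
#' missing trait, predictor or covariate are dropped (complete cases for this
#' model only); `n_used` records the rows kept.
#'
#' @param y Numeric trait vector.
#' @param predictor Numeric predictor vector (diagnosis 0/1 or additive
#'   genotype 0/1/2), non-constant on the used subjects.
#' @param Z Optional covariate data frame or matrix (e.g. age, sex,
#'   education), full rank together with the intercept.
#' @return One-row tibble: `beta`, `se`, `t`, `p`, `n_used`, `df`, and
#'   `gamma` (list column holding the intercept and covariate coefficients).
#' @examples
#' fit_linear_effect(c(1.0, 2.1, 2.9, 4.2, 4.8, 6.1), 0:5)
#' @export
fit_linear_effect <- function(y, predictor, Z = NULL) {
  y <- as.numeric(y)
  predictor <- as.numeric(predictor)
  if (length(y) != length(predictor)) {
    abort("`y` and `predictor` must have the same length.")
  }
  keep <- !is.na(y) & !is.na(predictor)
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)
    if (nrow(Z) != length(y)) abort("`Z` must have one row per subject.")
    keep <- keep & complete.cases(Z)
    Z <- Z[keep, , drop = FALSE]
  }
  fit <- .fit_multi(matrix(y[keep], ncol = 1), predictor[keep], Z)
  tibble(beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
         n_used = fit$n_used, df = fit$df, gamma = list(drop(fit$gamma)))
}

#' Define a case-control diagnostic contrast
#'
#' Selects the subjects of one diagnostic comparison (e.g. CN vs AD), codes
#' diagnosis 0 = control / 1 = case, and attaches their covariates.  All
#' alignment is by subject ID join, never by row order.
#'
#' @param diagnosis Tibble with `subject_id` and `diagnosis` label columns.
#' @param covariates Tibble with `subject_id` plus covariate columns.
#' @param control,case Diagnosis labels defining the contrast.  `case` may
#'   be a vector of labels pooled into one case group.
#' @param name Contrast label; default `"<control>-vs-<case>"`.
#' @return A `contrast` tibble: `subject_id`, `x` (0/1) and the covariate
#'   columns, restricted to subjects with both labels and covariates.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 50, n_rois = 5, n_snps = 2,
#'                                   seed = 3))
#' define_contrast(coh$diagnosis, coh$covariates, "CN", "AD")
#' @export
define_contrast <- function(diagnosis, covariates, control, case,
                            name = paste0(control, "-vs-",
                                          paste(case, collapse = "+"))) {
  for (nm in c("subject_id", "diagnosis")) {
    if (!nm %in% names(diagnosis)) abort(sprintf("`diagnosis` needs `%s`.", nm))
  }
  sel <- diagnosis |>
    dplyr::filter(.data$diagnosis %in% c(control, case)) |>
    dplyr::mutate(x = as.integer(.data$diagnosis %in% case)) |>
    dplyr::select("subject_id", "x") |>
    dplyr::inner_join(covariates, by = "subject_id")
  if (!nrow(sel)) abort("No subjects matched the contrast labels.")
  if (length(unique(sel$x)) < 2) {
    abort("Contrast must contain both controls and cases.")
  }
  structure(sel, class = c("contrast", class(sel)),
            contrast_name = name, control = control, case = case)
}

# Align trait rows to the contrast's subjects (ID join) and return the
# pieces every map fit needs.
.contrast_pieces <- function(qts, contrast) {
  if (!inherits(contrast, "contrast")) {
    abort("`contrast` must come from define_contrast().")
  }
  idx <- match(contrast$subject_id, qts$subject_id)
  if (anyNA(idx)) abort("Some contrast subjects are missing from the QT table.")
  Y <- .id_matrix(qts)[idx, , drop = FALSE]
  if (ncol(Y) < 3) abort("At least 3 ROIs are required for map analysis.")
  Z <- as.data.frame(contrast)[, setdiff(names(contrast), c("subject_id", "x")),
                               drop = FALSE]
  list(Y = Y, x = contrast$x, Z = Z,
       name = attr(contrast, "contrast_name"))
}

.as_effect_map <- function(df, roi_ids, contrast_name, n_fits,
                           invalid = character(0)) {
  structure(df, class = c("effect_map", class(df)),
            roi_ids = roi_ids, contrast = contrast_name,
            n_fits = n_fits, invalid_snps = invalid)
}

#' Diagnostic-effect significance map (step 1)
#'
#' Regresses every regional imaging trait on the 0/1 diagnosis of a contrast,
#' adjusting for the contrast's covariates, and records `-log10(p)` of the
#' diagnosis coefficient per ROI.
#'
#' @param qts Tibble with `subject_id` plus one numeric column per ROI.
#' @param contrast A [define_contrast()] object.
#' @return An `effect_map` tibble with one row per ROI: `predictor_id`,
#'   `roi_id`, `beta`, `se`, `t`, `p`, `neglog10_p`, `sign`, `n_used`.  ROI
#'   order follows the QT table and is kept as an attribute for alignment.
#' @seealso [snp_effect_maps()], [top_rois()]
#' @export
diagnosis_effect_map <- function(qts, contrast) {
  pieces <- .contrast_pieces(qts, contrast)
  fit <- .fit_multi(pieces$Y, pieces$x, pieces$Z)
  roi_ids <- colnames(pieces$Y)
  .as_effect_map(
    tibble(predictor_id = pieces$name, roi_id = roi_ids,
           beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
           neglog10_p = neglog10(fit$p), sign = sign(fit$beta),
           n_used = fit$n_used),
    roi_ids, pieces$name, n_fits = length(roi_ids))
}

#' Per-SNP genetic-effect significance maps (step 2)
#'
#' For each SNP, regresses every regional trait on the additive genotype over
#' the contrast's subjects (cases and controls pooled), adjusting for
#' covariates, giving one `-log10(p)` brain map per SNP.  With `s` SNPs and
#' `r` ROIs this performs exactly `s * r` regressions (recorded in the
#' `n_fits` attribute).  Subjects with a missing call are dropped per SNP.
#' SNPs constant on the contrast subjects cannot be fitted; they are excluded
#' with a warning and listed in the `invalid_snps` attribute.
#'
#' @inheritParams diagnosis_effect_map
#' @param genotypes Tibble with `subject_id` plus one 0/1/2 column per SNP
#'   (QC-passed).
#' @return An `effect_map` tibble stacking one map per SNP (rows: SNP x ROI).
#' @export
snp_effect_maps <- function(qts, genotypes, contrast) {
  pieces <- .contrast_pieces(qts, contrast)
  idx <- match(contrast$subject_id, genotypes$subject_id)
  if (anyNA(idx)) {
    abort("Some contrast subjects are missing from the genotype table.")
  }
  G <- .id_matrix(genotypes)[idx, , drop = FALSE]
  roi_ids <- colnames(pieces$Y)

  invalid <- character(0)
  maps <- purrr::map(colnames(G), function(s) {
    g <- G[, s]
    keep <- !is.na(g)
    if (sd(g[keep]) == 0 || sum(keep) <= ncol(pieces$Z) + 2) {
      invalid <<- c(invalid, s)
      return(NULL)
    }
    fit <- .fit_multi(pieces$Y[keep, , drop = FALSE], g[keep],
                      pieces$Z[keep, , drop = FALSE])
    tibble(predictor_id = s, roi_id = roi_ids,
           beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
           neglog10_p = neglog10(fit$p), sign = sign(fit$beta),
           n_used = fit$n_used)
  })
  if (length(invalid)) {
    warn(paste0("Excluded constant/unfittable SNP(s) in contrast subset: ",
                paste(invalid, collapse = ", ")))
  }
  out <- dplyr::bind_rows(maps)
  .as_effect_map(out, roi_ids, pieces$name,
                 n_fits = nrow(out), invalid = invalid)
}

#' Top-ranked regions of a significance map
#'
#' @param map An `effect_map` (single predictor).
#' @param n Number of regions to keep.
#' @return Tibble of the `n` most significant ROIs, ranked.
#' @export
top_rois <- function(map, n = 10) {
  map |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$neglog10_p)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    head(n)
}

#' Write significance maps as TSV
#'
#' Long format (`predictor_id`, `roi_id`, `beta`, `p`, `neglog10_p`, `sign`),
#' the file analogue of a full SNP-by-ROI p-value supplement.
#'
#' @param map An `effect_map`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_effect_map <- function(map, path) {
  readr::write_tsv(
    as_tibble(map)[c("predictor_id", "roi_id", "beta", "p", "neglog10_p",
                     "sign", "n_used")],
    path)
  invisible(path)
}

#' Heatmap of significance maps
#'
#' Predictor-by-ROI tile plot of `-log10(p)`, the usual way to eyeball which
#' regions drive each SNP's or the diagnosis' signal.
#'
#' @param object An `effect_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.effect_map <- function(object, ...) {
  df <- as_tibble(object)
  df$roi_id <- factor(df$roi_id, levels = attr(object, "roi_ids"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_id, y = .data$predictor_id,
                                   fill = .data$neglog10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "ROI", y = NULL,
                  title = paste0("Significance map (", attr(object, "contrast"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
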