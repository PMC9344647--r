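# Readers for the tabular interchange formats: genotypes (VCF or
# additive-dosage TSV), imaging traits, covariates and diagnosis labels.
# Subjects are always matched by ID join, never by row order.

#' Read a genotype matrix
#'
#' Reads genotypes either from a VCF (GT field, biallelic records only,
#' missing as `./.`) or from an additive-dosage TSV (one `subject_id` column
#' plus one 0/1/2 column per SNP).  After reading, every SNP is folded to
#' minor-allele coding: when the counted allele's frequency among non-missing
#' subjects exceeds 0.5 the column is flipped (`g` to `2 - g`), so both
#' formats yield the same matrix for the same data.  Association p-values are
#' invariant to this fold; only coefficient signs depend on it.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param missing_token Token marking a missing call in TSV input (besides an
#'   empty field); default `"NA"`.
#' @return Tibble with `subject_id` plus one integer column per SNP.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           missing_token = "NA") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") .read_genotypes_vcf(path) else {
    .read_genotypes_tsv(path, missing_token)
  }
  if (anyDuplicated(out$subject_id)) {
    abort("Duplicate subject IDs in the genotype file.")
  }
  .fold_to_minor(out)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    abort(paste0("Multi-allelic VCF record(s) are not supported: ",
                 paste(fix[multi, "ID"], collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(fix[, "ID"], names(gt)))
  gtc <- gsub("\\|", "/", gt)
  lookup <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  malformed <- !is.na(gtc) & !(gtc %in% c(names(lookup), "./.", "."))
  if (any(malformed)) abort("Malformed GT field(s) in VCF.")
  vals <- unname(lookup[gtc])
  m <- matrix(vals, nrow = nrow(gt))  # SNP x subject
  m <- t(m)
  dimnames(m) <- list(colnames(gt), rownames(gt))
  dplyr::bind_cols(tibble(subject_id = rownames(m)), as_tibble(m))
}

.read_genotypes_tsv <- function(path, missing_token) {
  df <- readr::read_tsv(path, na = c("", missing_token),
                        show_col_types = FALSE)
  if (!"subject_id" %in% names(df)) {
    abort("Genotype TSV must have a `subject_id` column.")
  }
  vals <- as.matrix(df[setdiff(names(df), "subject_id")])
  if (any(!is.na(vals) & !(vals %in% 0:2))) {
    abort("Genotype TSV entries must be 0, 1, 2 or missing.")
  }
  df
}

.fold_to_minor <- function(genotypes) {
  G <- .id_matrix(genotypes)
  flip <- apply(G, 2, function(g) {
    gg <- g[!is.na(g)]
    length(gg) > 0 && sum(gg) / (2 * length(gg)) > 0.5
  })
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  dplyr::bind_cols(
    tibble(subject_id = rownames(G)),
    as_tibble(matrix(as.integer(G), nrow(G), dimnames = dimnames(G)))
  )
}

#' Read an imaging-trait, covariate or diagnosis table
#'
#' TSVs keyed by a `subject_id` column.  `read_covariates()` additionally
#' maps a character `sex` column through `sex_map` (default M/F and 0/1 to
#' numeric 0/1).
#'
#' @param path Input file.
#' @return A tibble keyed by `subject_id`.
#' @export
read_qts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(df)) abort("QT TSV must have `subject_id`.")
  if (ncol(df) < 4) abort("At least 3 ROI columns are required.")
  if (anyDuplicated(df$subject_id)) abort("Duplicate subject IDs in QT file.")
  df
}

#' @rdname read_qts
#' @param sex_map Named numeric vector mapping sex tokens to 0/1.
#' @export
read_covariates <- function(path, sex_map = c(M = 1, F = 0, `1` = 1, `0` = 0)) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(df)) {
    abort("Covariate TSV must have `subject_id`.")
  }
  if ("sex" %in% names(df)) {
    tok <- as.character(df$sex)
    if (any(!tok %in% names(sex_map))) {
      abort("Unrecognised sex token; extend `sex_map`.")
    }
    df$sex <- unname(sex_map[tok])
  }
  df
}

#' @rdname read_qts
#' @export
read_diagnosis <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  if (!all(c("subject_id", "diagnosis") %in% names(df))) {
    abort("Diagnosis TSV must have `subject_id` and `diagnosis` columns.")
  }
  df
}
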