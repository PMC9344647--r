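# Shared validation helpers and small numeric primitives.

# Underflow floor for p-values before the -log10 transform.  OLS t-tests on
# exact fits can underflow to 0; the floor keeps maps finite.  Configurable
# through the `floor` argument of neglog10().
.P_FLOOR <- 1e-300

#' Negative log10 transform of a p-value
#'
#' Maps a p-value to the significance scale used throughout the package:
#' `-log10(p)`.  Values below the underflow floor are clamped to the floor
#' before the transform, so an exactly-zero (underflowed) p-value yields a
#' large finite map entry rather than `Inf`.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (zeros are treated as
#'   underflow and clamped).
#' @param floor Positive clamp applied before the transform (default
#'   `1e-300`, i.e. a ceiling of 300 on the returned scale).
#' @return Numeric vector of `-log10(p)`, non-negative.
#' @examples
#' neglog10(c(0.01, 1, 1e-320))
#' @export
neglog10 <- function(p, floor = .P_FLOOR) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1] (values below the floor are clamped).")
  }
  -log10(pmax(p, floor))
}

#' Bonferroni correction
#'
#' Multiplies a raw p-value by the declared family size and caps at 1.
#'
#' @param p_raw Numeric vector of raw p-values in `(0, 1]`.
#' @param m Family size (number of tests), a single number `>= 1`.
#' @return `pmin(1, m * p_raw)`.
#' @examples
#' bonferroni(0.001, 54)
#' @export
bonferroni <- function(p_raw, m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1) {
    abort("`m` must be a single number >= 1.")
  }
  if (any(p_raw <= 0 | p_raw > 1, na.rm = TRUE)) {
    abort("`p_raw` must lie in (0, 1].")
  }
  pmin(1, m * p_raw)
}

# One global seed drives all module streams; submodules draw from streams
# derived by fixed offsets so each stage is reproducible in isolation.
# Offsets stay well below 2^31.
.split_seed <- function(seed, which) {
  offsets <- c(genotypes = 11L, covariates = 23L, qts = 37L,
               liability = 53L, nullsets = 71L)
  (as.integer(seed) + offsets[[which]]) %% .Machine$integer.max
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name, if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

# Extract a numeric matrix (subjects x variables) from an id-keyed tibble.
# Row names carry the subject ids; column order is preserved.
.id_matrix <- function(df, id_col = "subject_id") {
  if (!is.data.frame(df)) abort("Expected a data frame.")
  if (!id_col %in% names(df)) {
    abort(sprintf("Column `%s` is required.", id_col))
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) abort("Duplicate subject IDs.")
  m <- as.matrix(df[setdiff(names(df), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
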