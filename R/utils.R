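# Internal helpers shared across modules.

# Convert a gene-by-sample tibble (gene_id + numeric sample columns) to a
# numeric matrix with gene_id rownames. The first column must be `gene_id`.
expr_to_matrix <- function(x, what = "matrix") {
  if (!is.data.frame(x) || !"gene_id" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `gene_id` column.", what))
  }
  if (anyDuplicated(x$gene_id)) {
    abort(sprintf("`%s` has duplicated gene_id values.", what))
  }
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  if (!is.numeric(m)) {
    abort(sprintf("`%s` has non-numeric sample columns.", what))
  }
  if (anyNA(m)) abort(sprintf("`%s` contains missing values.", what))
  rownames(m) <- x$gene_id
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m, rownames = "gene_id")
  out
}

# Validate a scalar fraction field, naming the offending field on failure.
check_fraction <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1] (got %s).",
                  field, deparse(value)))
  }
  invisible(value)
}

check_positive <- function(value, field, strict = TRUE) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    (if (strict) value > 0 else value >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number (got %s).",
                  field, if (strict) "positive" else "non-negative",
                  deparse(value)))
  }
  invisible(value)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

`%||%` <- rlang::`%||%`
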