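#' Convert read counts to RPKM
#'
#' Reads per kilobase of exon model per million mapped reads:
#' \deqn{\mathrm{RPKM}_{gs} = 10^9 \, c_{gs} / (L_g \, N_s)}
#' with exon-model length \eqn{L_g} in bp and library size \eqn{N_s} taken as
#' the column sum of the analysed count matrix.
#'
#' @param counts Tibble: `gene_id` + one non-negative integer column per
#'   sample.
#' @param annotation Tibble with `gene_id` and `length_bp`; every gene in
#'   `counts` must be annotated.
#' @return Tibble of RPKM values, same shape and labels as `counts`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10L, 999990L))
#' ann <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(2000L, 1000L))
#' compute_rpkm(counts, ann) # g1: 1e9 * 10 / (2000 * 1e6) = 5
#' @export
compute_rpkm <- function(counts, annotation) {
  m <- expr_to_matrix(counts, "counts")
  if (any(m < 0)) abort("`counts` contains negative values.")
  check_columns(annotation, c("gene_id", "length_bp"), "`annotation`")
  if (any(annotation$length_bp < 1)) abort("`length_bp` must be >= 1.")
  missing <- setdiff(rownames(m), annotation$gene_id)
  if (length(missing)) {
    abort(sprintf("No annotation for gene_id(s): %s.",
                  paste(head(missing, 10), collapse = ", ")))
  }
  len <- annotation$length_bp[match(rownames(m), annotation$gene_id)]
  libsize <- colSums(m)
  if (any(libsize <= 0)) {
    abort(sprintf("Zero library size in sample(s): %s.",
                  paste(colnames(m)[libsize <= 0], collapse = ", ")))
  }
  rpkm <- 1e9 * m / (len * rep(libsize, each = nrow(m)))
  matrix_to_expr(rpkm)
}

#' Filter to expressed genes
#'
#' Keeps gene g when RPKM strictly exceeds `threshold` in at least
#' `min_fraction` of the samples — the conventional "RPKM > 4 in at least 50%
#' of samples" detection rule. The threshold comparison is strict (`>`), the
#' fraction comparison inclusive (`>=`).
#'
#' @param rpkm RPKM tibble from [compute_rpkm()].
#' @param threshold RPKM detection threshold (strict).
#' @param min_fraction Minimum fraction of samples above threshold.
#' @param quiet Suppress the retained/total message.
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expressed <- function(rpkm, threshold = 4, min_fraction = 0.5,
                             quiet = FALSE) {
  m <- expr_to_matrix(rpkm, "rpkm")
  if (nrow(m) == 0L || ncol(m) == 0L) abort("`rpkm` is empty.")
  check_fraction(min_fraction, "min_fraction")
  keep <- rowMeans(m > threshold) >= min_fraction
  if (!quiet) {
    inform(sprintf("filter_expressed: retained %d of %d genes (RPKM > %g in >= %g%% of %d samples).",
                   sum(keep), nrow(m), threshold, 100 * min_fraction, ncol(m)))
  }
  rownames(m)[keep]
}

#' Row-wise z-score transform
#'
#' Standardises each gene across samples: `(x - mean) / sd` with the sample
#' (n - 1) standard deviation, the transform conventionally applied to RPKM
#' before drawing expression heatmaps. Constant rows become all zeros with a
#' warning rather than NaN.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param genes Optional character vector restricting (and ordering) the rows.
#' @return Tibble of z-scores with the same columns.
#' @export
zscore_rows <- function(expr, genes = NULL) {
  m <- expr_to_matrix(expr, "expr")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(sprintf("Gene(s) not in `expr`: %s.",
                    paste(head(missing, 10), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2L) abort("z-scores need at least two samples per row.")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  constant <- s == 0
  if (any(constant)) {
    warn(sprintf("%d constant row(s) mapped to all-zero z-scores.",
                 sum(constant)))
    s[constant] <- 1
  }
  matrix_to_expr((m - mu) / s)
}

#' Principal component analysis of samples
#'
#' SVD-based PCA treating samples as observations and genes as variables;
#' gene dimensions are centred across samples but not rescaled (the intended
#' input is an already z-scored matrix).
#'
#' @param x Expression or z-score tibble (`gene_id` + sample columns).
#' @param n_components Number of components to return; at most
#'   `min(genes, samples)`.
#' @return A list of class `pca_result`:
#'   `scores` (tibble `sample_id`, `PC1`, ...), `loadings` (tibble `gene_id`,
#'   `PC1`, ...), `var_explained` (tibble `component`, `var_explained`,
#'   non-increasing fractions summing to <= 1).
#' @export
pca_scores <- function(x, n_components = 2) {
  m <- expr_to_matrix(x, "x")
  kmax <- min(dim(m))
  if (!is.numeric(n_components) || n_components < 1 || n_components > kmax) {
    abort(sprintf("`n_components` must be in [1, %d].", kmax))
  }
  k <- as.integer(n_components)
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = as_tibble(fit$x[, seq_len(k), drop = FALSE],
                         rownames = "sample_id"),
      loadings = as_tibble(fit$rotation[, seq_len(k), drop = FALSE],
                           rownames = "gene_id"),
      var_explained = tibble(component = paste0("PC", seq_len(k)),
                             var_explained = ve[seq_len(k)])
    ),
    class = "pca_result"
  )
}
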