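#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned in
#' the original order. Ties are handled by a stable sort; tied p-values share
#' the larger index's factor through the running minimum.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.02)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) {
    abort("`p` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must be finite and in [0, 1].")
  }
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Per-gene two-group contrast on log-transformed RPKM
#'
#' For each gene in the universe, the log2 fold change is the difference of
#' group means of `log2(RPKM + pseudocount)` (comparison minus reference) and
#' the p-value comes from a two-sided Welch unequal-variance t-test on the
#' same transformed values; q-values are BH-adjusted across the universe.
#' The test operates at the RPKM level rather than fitting a count model, so
#' the statistic can be swapped without touching the classifiers downstream.
#'
#' Degenerate genes with zero variance in both groups get p = 1 when the
#' means agree (log2 fold change 0) and p = 0 when they differ.
#'
#' @param expr RPKM tibble from [compute_rpkm()].
#' @param sample_sheet Tibble with `sample_id` and `group` covering the
#'   samples of `expr`.
#' @param reference,comparison Group labels; the fold change is
#'   comparison - reference. Each needs >= 2 samples.
#' @param genes Gene universe (ordered gene ids); default all genes in
#'   `expr`.
#' @param name Contrast label stored on the result; default
#'   `"<comparison>_vs_<reference>"`.
#' @param pseudocount Added before the log2 transform.
#' @return A `contrast_tbl`: tibble with `gene_id`, `log2_fc`, `p_raw`,
#'   `q_bh` in universe order, carrying `contrast`, `reference` and
#'   `comparison` attributes.
#' @export
contrast_test <- function(expr, sample_sheet, reference, comparison,
                          genes = NULL, name = NULL, pseudocount = 1) {
  m <- expr_to_matrix(expr, "expr")
  check_columns(sample_sheet, c("sample_id", "group"), "`sample_sheet`")
  genes <- genes %||% rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    abort(sprintf("Gene(s) in universe but not in `expr`: %s.",
                  paste(head(missing, 10), collapse = ", ")))
  }
  if (length(genes) == 0L) abort("Empty gene universe.")
  samples_of <- function(g) {
    ids <- sample_sheet$sample_id[sample_sheet$group == g]
    ids <- intersect(colnames(m), ids)
    if (length(ids) < 2L) {
      abort(sprintf("Group '%s' has %d sample(s) in `expr`; need >= 2.",
                    g, length(ids)))
    }
    ids
  }
  ref_ids <- samples_of(reference)
  cmp_ids <- samples_of(comparison)

  x <- log2(m[genes, ref_ids, drop = FALSE] + pseudocount)
  y <- log2(m[genes, cmp_ids, drop = FALSE] + pseudocount)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t_stat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(t_stat), df)
  # zero variance in both groups: p determined by whether the means agree
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  out <- tibble(gene_id = genes, log2_fc = unname(lfc),
                p_raw = unname(p), q_bh = bh_adjust(unname(p)))
  new_contrast_tbl(out,
                   contrast = name %||% paste0(comparison, "_vs_", reference),
                   reference = reference, comparison = comparison)
}

new_contrast_tbl <- function(x, contrast, reference = NA_character_,
                             comparison = NA_character_) {
  structure(x,
            contrast = contrast, reference = reference,
            comparison = comparison,
            class = c("contrast_tbl", class(tibble())))
}
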