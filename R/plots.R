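# ggplot2 views of the main result types. These are working plots for
# QC and exploration, not figure-quality graphics.

#' Kaplan-Meier survival curves
#'
#' Step curves per arm from [km_curve()], with censoring-free convention
#' (curves drop only at observed deaths).
#'
#' @inheritParams km_curve
#' @return A ggplot.
#' @export
plot_km <- function(data, arms = NULL) {
  curve <- km_curve(data, arms)
  start <- dplyr::distinct(curve, .data$arm)
  start <- dplyr::mutate(start, time = 0, survival = 1)
  curve <- dplyr::bind_rows(start, curve)
  ggplot2::ggplot(curve, ggplot2::aes(.data$time, .data$survival,
                                      colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival", colour = "Arm")
}

#' Volcano plot of a contrast
#'
#' @param contrast A `contrast_tbl`.
#' @param fdr Genes with `q_bh` below this are highlighted.
#' @return A ggplot.
#' @export
plot_volcano <- function(contrast, fdr = 0.1) {
  d <- dplyr::mutate(as_tibble(contrast), significant = .data$q_bh < fdr)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p_raw),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(title = attr(contrast, "contrast"),
                  x = "log2 fold change", y = "-log10 raw p",
                  colour = sprintf("FDR < %g", fdr))
}

#' Heatmap of row z-scores
#'
#' Tile heatmap of a z-scored expression matrix, genes by samples; typically
#' fed the reverted or DEG gene set.
#'
#' @param z Z-score tibble from [zscore_rows()].
#' @param sample_order Optional ordering of the sample columns.
#' @return A ggplot.
#' @export
plot_zscore_heatmap <- function(z, sample_order = NULL) {
  long <- tidyr::pivot_longer(z, -"gene_id", names_to = "sample_id",
                              values_to = "zscore")
  if (!is.null(sample_order)) {
    long$sample_id <- factor(long$sample_id, levels = sample_order)
  }
  long$gene_id <- factor(long$gene_id, levels = rev(unique(z$gene_id)))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene_id,
                                     fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn pca_scores Scatter plot of the first two sample scores,
#'   optionally coloured by a sample-sheet column.
#' @param object A `pca_result`.
#' @param sample_sheet Optional sample sheet joined on `sample_id`.
#' @param colour Column of `sample_sheet` to colour by (default `group`).
#' @param ... Unused.
#' @export
autoplot.pca_result <- function(object, sample_sheet = NULL,
                                colour = "group", ...) {
  d <- object$scores
  mapping <- ggplot2::aes(.data$PC1, .data$PC2)
  if (!is.null(sample_sheet)) {
    d <- dplyr::left_join(d, sample_sheet, by = "sample_id")
    mapping <- ggplot2::aes(.data$PC1, .data$PC2,
                            colour = .data[[colour]])
  }
  ve <- object$var_explained$var_explained
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
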