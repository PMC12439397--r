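#' Volcano-style overview of a differential expression result
#'
#' One panel per cell type: log2 fold change against -log10 p, significant
#' genes (smallest FDR cutoff of the design) highlighted.
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  cutoff <- min(object$design$fdr_cutoffs)
  tab <- dplyr::mutate(object$table, significant = .data$fdr < cutoff)
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", cutoff)) +
    ggplot2::labs(x = "log2 fold change (group A vs B)",
                  y = expression(-log[10] ~ p))
}

#' Violin plot of correlation distributions by pair class
#'
#' @param records Correlation records (one or several cell types).
#' @return A ggplot object.
#' @export
plot_correlation_violins <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$pair_class, .data$r,
                                        fill = .data$pair_class)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.08, size = 0.6, alpha = 0.5) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "patient-pair class", y = "Pearson r")
}

#' Dotplot of gene expression by cell type and group
#'
#' Dot colour encodes the group mean of the aggregated expression, dot size
#' the fraction of the group's patients expressing the gene.
#'
#' @param summary A [dotplot_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$cell_type, .data$gene,
                               colour = .data$mean_expr,
                               size = .data$frac_patients)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_size_area(max_size = 5, name = "fraction of patients") +
    ggplot2::scale_colour_viridis_c(name = "mean expression") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Score plot of a NIPALS PCA
#'
#' @param object A `nipals_pca` result.
#' @param components Two components to plot (default PC1/PC2).
#' @param groups Optional named group vector for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipals_pca <- function(object, components = c(1, 2), groups = NULL,
                                ...) {
  s <- object$scores[, components, drop = FALSE]
  d <- tibble::as_tibble(s, rownames = "sample")
  names(d)[2:3] <- c("x", "y")
  if (!is.null(groups)) d$group <- unname(groups[d$sample])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = colnames(s)[1], y = colnames(s)[2])
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}
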