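#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of differential statistics
#'
#' @param x A [deg_stats()] tibble.
#' @param fdr_cut,fc_cut Thresholds drawn as guides and used to color
#'   called genes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_results
#' @export
autoplot.deg_results <- function(x, fdr_cut = 0.05, fc_cut = 1.5, ...) {
  d <- dplyr::mutate(tibble::as_tibble(x),
                     called = .data$p_fdr < fdr_cut &
                       (is.null(fc_cut) | abs(.data$fold_change) > fc_cut))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = -log10(.data$p_raw),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "DEG") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Heatmap of a panel co-expression grid
#'
#' @param rho Symmetric correlation matrix from
#'   [spearman_panel_correlation()].
#' @return A ggplot tile map.
#' @export
plot_panel_correlation <- function(rho) {
  d <- as.data.frame(as.table(rho), responseName = "rho")
  names(d)[1:2] <- c("gene_a", "gene_b")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_a, y = .data$gene_b, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Confusion-grid heatmap for a cross-validation summary
#'
#' @param x A `cv_confusion` object.
#' @param ... Unused.
#' @return A ggplot tile map of repeat-averaged counts.
#' @method autoplot cv_confusion
#' @export
autoplot.cv_confusion <- function(x, ...) {
  d <- tidy(x)
  classes <- x$config$classes
  d$predicted <- factor(d$predicted, levels = classes)
  d$truth <- factor(d$truth, levels = classes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                  fill = .data$mean_count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$mean_count, 1))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", name = "mean count") +
    ggplot2::labs(x = "truth", y = "predicted") +
    ggplot2::theme_minimal()
}

#' Group distribution of PRF scores
#'
#' @param x A `prf_scores` tibble with a `status` column.
#' @param ... Unused.
#' @return A ggplot box plot of PRF by group.
#' @method autoplot prf_scores
#' @export
autoplot.prf_scores <- function(x, ...) {
  stopifnot("status" %in% names(x))
  d <- tibble::as_tibble(x)
  d$status <- factor(d$status, levels = c("NS", "SMK", "COPD"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data$prf, fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, show.legend = FALSE) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = NULL, y = "PRF index (log scale)") +
    ggplot2::theme_minimal()
}
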