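## ggplot2 views of spectra and the clustered correlation matrix.

#' Heat map of the clustered correlation matrix
#'
#' Centers of one cluster are placed next to each other (see
#' [heatmap_order()]); the fill runs red (negative) through black (zero)
#' to green (positive), the conventional palette for correlation
#' structure.
#'
#' @param corr Correlation matrix.
#' @param partition Optional `careflow_partition` controlling the block
#'   ordering.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr, partition = NULL) {
  ord <- if (is.null(partition)) rownames(corr) else heatmap_order(corr, partition)
  df <- tibble::as_tibble(as.table(corr[ord, ord]), .name_repair = "minimal")
  names(df) <- c("row", "col", "correlation")
  df$row <- factor(df$row, levels = rev(ord))
  df$col <- factor(df$col, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black", high = "green",
                                  midpoint = 0, limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Stacked pathway-spectrum bars per center
#'
#' @param object A `careflow_spectra` table.
#' @param ... Unused.
#' @return A ggplot object: one stacked bar of type shares per center.
#' @export
autoplot.careflow_spectra <- function(object, ...) {
  m <- spectrum_matrix(object, "ratio")
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("center_id", "series_type", "share")
  df$series_type <- factor(df$series_type, levels = rev(series_types()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_id, y = .data$share,
                                   fill = .data$series_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "center", y = "share of event series", fill = "type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
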