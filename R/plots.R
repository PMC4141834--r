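#' Heat plot of a community matrix
#'
#' Rows (OTUs) are z-scored across arrays before display (the standard
#' heat-plot scaling: subtract the row mean, divide by the row standard
#' deviation), so colours compare an OTU across samples, not OTUs to each
#' other.
#'
#' @param object A [community_matrix()].
#' @param row_scale Apply [row_zscore()] first (default TRUE; ignored when
#'   the matrix is already `row_z`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.community_matrix <- function(object, row_scale = TRUE, ...) {
  m <- object
  if (row_scale && m$kind != "row_z") m <- suppressWarnings(row_zscore(m))
  df <- tidy.community_matrix(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$array_id, y = .data$otu_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = if (m$kind == "row_z") "z" else m$kind) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param axes Which two axes to plot (default P1 vs P2).
#' @param groups Optional group labels (named by array id, or a
#'   (id, group) data frame) used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, axes = c(1, 2), groups = NULL, ...) {
  ax <- paste0("P", axes)
  df <- object$coordinates
  if (!all(ax %in% names(df))) pc_stop("requested axes not available")
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- stats::setNames(as.character(groups[[2]]), groups[[1]])
    }
    df$group <- unname(groups[df$array_id])
  }
  lab <- sprintf("%s (%.1f%%)", ax, object$pct_variation[axes])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]],
                                        y = .data[[ax[2]]])) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_bw()
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
}

#' Bar plot of the strongest indicator OTUs
#'
#' @param object An `indval_result`.
#' @param n Number of top OTUs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.indval_result <- function(object, n = 20, ...) {
  df <- utils::head(object$summary, n)
  df$otu_id <- factor(df$otu_id, levels = rev(df$otu_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indval, y = .data$otu_id,
                                   fill = .data$best_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "indicator value", y = NULL, fill = "group") +
    ggplot2::theme_minimal()
}
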