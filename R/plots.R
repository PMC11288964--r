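#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_tile
#'   geom_hline geom_vline labs scale_fill_gradient2 theme_minimal
#'   scale_colour_manual coord_equal
NULL

#' PCA score plot with prediction ellipses
#'
#' @param object a `ribor_pca` object.
#' @param groups optional sample-to-group mapping; colours the points and,
#'   for groups with at least 3 samples, draws the prediction ellipses.
#' @param prob ellipse coverage probability.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ribor_pca <- function(object, groups = NULL, prob = 0.95, ...) {
  sc <- object$scores
  ev <- round(100 * object$explained_var[1:2], 1)
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    labs(
      x = paste0("PC1 (", ev[1], "%)"),
      y = paste0("PC2 (", ev[2], "%)")
    ) +
    theme_minimal()
  if (is.null(groups)) {
    return(p + geom_point())
  }
  gt <- as_groups_tbl(groups)
  sc <- dplyr::inner_join(sc, gt, by = "sample")
  p <- p + geom_point(data = sc, aes(colour = .data$group))
  big <- names(which(table(sc$group) >= 3))
  if (length(big) > 0) {
    ell <- prediction_ellipse(object$scores, gt[gt$group %in% big, ],
                              prob = prob)
    p <- p + geom_path(
      data = ellipse_outline(ell),
      aes(x = .data$x, y = .data$y, colour = .data$group)
    )
  }
  p
}

#' Correlation heatmap
#'
#' @param object a `ribor_cor` object.
#' @param order optional sample ordering (e.g. `sample_tree$labels[
#'   sample_tree$order]` from a pipeline run).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ribor_cor <- function(object, order = NULL, ...) {
  d <- tidy(object)
  lv <- order %||% object$sample_ids
  d$sample_1 <- factor(d$sample_1, levels = lv)
  d$sample_2 <- factor(d$sample_2, levels = lv)
  ggplot(d, aes(x = .data$sample_1, y = .data$sample_2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, limits = c(-1, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal()
}

#' Volcano plot
#'
#' Effect size (log2 fold change of group mean ratios) against significance
#' (-log10 adjusted p), coloured by direction call.
#'
#' @param object a `ribor_diff` table.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ribor_diff <- function(object, ...) {
  v <- volcano_table(object)
  alpha <- attr(object, "alpha")
  ggplot(v, aes(x = .data$log2fc, y = .data$neg_log10_p_adj,
                colour = .data$direction)) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    scale_colour_manual(
      values = c(up = "#B2182B", down = "#2166AC", ns = "grey60")
    ) +
    labs(x = "log2 fold change of mean ratio",
         y = "-log10 adjusted p") +
    theme_minimal()
}

#' Scaled-ratio heatmap with dendrogram ordering
#'
#' @param scaled row-scaled tibble from [scale_rows()].
#' @param row_tree,col_tree optional [stats::hclust] trees used to order the
#'   axes (e.g. from [average_linkage()]).
#' @return A ggplot.
#' @export
plot_ratio_heatmap <- function(scaled, row_tree = NULL, col_tree = NULL) {
  m <- qt_matrix(scaled)
  row_lv <- if (!is.null(row_tree)) {
    row_tree$labels[row_tree$order]
  } else {
    rownames(m)
  }
  col_lv <- if (!is.null(col_tree)) {
    col_tree$labels[col_tree$order]
  } else {
    colnames(m)
  }
  d <- tidyr::pivot_longer(scaled, -1, names_to = "sample",
                           values_to = "z")
  names(d)[1] <- "protein"
  d$protein <- factor(d$protein, levels = row_lv)
  d$sample <- factor(d$sample, levels = col_lv)
  ggplot(d, aes(x = .data$sample, y = .data$protein, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "row z") +
    theme_minimal()
}
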