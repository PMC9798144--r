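# Functional plots: stoichiometry heatmap and PCA condition map.

#' Heatmap of the stoichiometry matrix
#'
#' Sites and conditions hierarchically clustered on Euclidean distance
#' (complete linkage), colors on the \[0,1\] stoichiometry scale.
#'
#' @param sm a [build_matrix()] result.
#' @param filename optional file to write the plot to (passed to
#'   [pheatmap::pheatmap()]).
#' @param ... further arguments to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_stoichiometry_heatmap <- function(sm, filename = NA, ...) {
  m <- if (inherits(sm, "stoich_matrix")) sm$matrix else as.matrix(sm)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  ph <- pheatmap::pheatmap(
    m, clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean", clustering_method = "complete",
    breaks = seq(0, 1, length.out = 101), filename = filename,
    silent = !is.na(filename), ...)
  invisible(ph)
}

#' Plot conditions on two principal components
#'
#' @param pca a [run_pca()] result.
#' @param conditions a [condition_map()] (for color/shape aesthetics).
#' @param components which two components to draw (default 1:2).
#' @return a ggplot object.
#' @export
plot_pca <- function(pca, conditions, components = c(1, 2)) {
  stopifnot(inherits(pca, "mod_pca"), length(components) == 2)
  conditions <- condition_map(conditions)
  df <- as_tibble(pca$coords[, components, drop = FALSE],
                  rownames = "condition") %>%
    left_join(conditions %>%
                distinct(.data$condition, .data$species, .data$cell_line,
                         .data$treatment),
              by = "condition")
  names(df)[2:3] <- c("x", "y")
  lab <- sprintf("PC%d (%.1f%%)", components,
                 100 * pca$var_explained[components])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   color = .data$species,
                                   shape = .data$cell_line)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2], color = "RNA species",
                  shape = "cell line") +
    ggplot2::theme_minimal()
}
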