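#' Plot pairwise sample similarities by variance class
#'
#' Boxplot of the pairwise Pearson correlations underlying a
#' [class_summary()], one box per comparison class.
#'
#' @param variation An `mp_variation` object.
#' @return A ggplot object.
#' @export
plot_variation <- function(variation) {
  pairs <- attr(variation, "pairs")
  ggplot2::ggplot(
    pairs, ggplot2::aes(x = .data$class, y = .data$r, fill = .data$class)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "Pearson correlation",
      title = "Sample similarity by comparison class"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mp_variation <- function(object, ...) plot_variation(object)

#' PCA score plot of runs
#'
#' @param object An `mp_pca` object from [pca_runs()].
#' @param runs Optional run annotation to colour by subject and shape by
#'   time point.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_pca <- function(object, runs = NULL, ...) {
  scores <- object$scores
  pv <- object$percent_variance
  if (!is.null(runs)) {
    scores <- left_join(scores, as_tibble(runs), by = "run_id")
    p <- ggplot2::ggplot(scores, ggplot2::aes(
      x = .data$PC1, y = .data$PC2,
      colour = .data$subject, shape = .data$timepoint
    ))
  } else {
    p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pv[1]),
      y = sprintf("PC2 (%.1f%%)", pv[2])
    ) +
    ggplot2::theme_minimal()
}

#' Dendrogram plot on correlation distance
#'
#' Draws an [stats::hclust] tree (distance `1 - r` on the vertical axis)
#' with ggplot2.
#'
#' @param hc An hclust object, e.g. from [hcluster()].
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(hc) {
  hc <- stats::as.hclust(hc)
  n <- length(hc$labels)
  x_leaf <- match(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  seg <- list()
  pos <- function(k) {
    if (k < 0) c(x = x_leaf[-k], y = 0) else c(x = node_x[k], y = node_y[k])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1])
    b <- pos(hc$merge[i, 2])
    node_x[i] <- mean(c(a["x"], b["x"]))
    seg[[length(seg) + 1L]] <- tibble(
      x = c(a[["x"]], a[["x"]], b[["x"]]),
      xend = c(a[["x"]], b[["x"]], b[["x"]]),
      y = c(a[["y"]], node_y[i], node_y[i]),
      yend = c(node_y[i], node_y[i], a[["y"]] * 0 + b[["y"]])
    )
  }
  segs <- bind_rows(seg)
  labs_df <- tibble(x = x_leaf, label = hc$labels)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::geom_text(
      data = labs_df,
      ggplot2::aes(x = .data$x, y = -0.02, label = .data$label),
      angle = 90, hjust = 1, size = 3
    ) +
    ggplot2::scale_y_continuous("1 - Pearson correlation") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal() +
    ggplot2::theme(plot.margin = ggplot2::margin(5, 5, 40, 5))
}

#' Stacked-bar plot of a taxonomic composition
#'
#' @param composition Tibble from [aggregate_taxa()] or, for per-sample
#'   bars, a tibble with additional `sample_id`.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  composition <- as_tibble(composition)
  if ("sample_id" %in% names(composition)) {
    p <- ggplot2::ggplot(composition, ggplot2::aes(
      x = .data$sample_id, y = .data$percent, fill = .data$taxon
    ))
  } else {
    p <- ggplot2::ggplot(composition, ggplot2::aes(
      x = "all spectra", y = .data$percent, fill = .data$taxon
    ))
  }
  p +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of spectra", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of the COG ranking
#'
#' @param ranking Tibble from [rank_cogs()].
#' @return A ggplot object.
#' @export
plot_cog_ranking <- function(ranking) {
  ranking <- as_tibble(ranking)
  ggplot2::ggplot(ranking, ggplot2::aes(
    x = stats::reorder(.data$cog_id, .data$percent_of_core_spectra),
    y = .data$percent_of_core_spectra
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of core spectra") +
    ggplot2::theme_minimal()
}

#' Heatmap of enriched associations per genus and COG category
#'
#' Tile plot of `log10(n)` significant protein-genus associations per COG
#' functional category, the usual colour-keyed summary display.
#'
#' @param assoc_categories Tibble from [summarize_categories()].
#' @return A ggplot object.
#' @export
plot_association_heatmap <- function(assoc_categories) {
  x <- as_tibble(assoc_categories)
  x$log10_n <- log10(pmax(x$n_associations, 1e-3))
  ggplot2::ggplot(x, ggplot2::aes(
    x = .data$category, y = .data$genus, fill = .data$log10_n
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(associations)") +
    ggplot2::labs(x = "COG category", y = NULL) +
    ggplot2::theme_minimal()
}
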