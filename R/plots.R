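# ggplot2 displays for the main result types.

#' Plot per-trait diversity statistics
#'
#' Bar panels of the coefficient of variation and the Shannon-Wiener index
#' per trait.
#'
#' @param object A `trait_diversity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_diversity
#' @export
autoplot.trait_diversity <- function(object, ...) {
  df <- object$summary |>
    dplyr::select("trait", `CV (%)` = "cv", `H' (nats)` = "h") |>
    tidyr::pivot_longer(-"trait", names_to = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Quantitative-trait variation and diversity") +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram with an optional cut line
#'
#' @param object A `marker_dendrogram`.
#' @param cut Optional cut height drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_dendrogram
#' @export
autoplot.marker_dendrogram <- function(object, cut = NULL, ...) {
  seg <- dendro_segments(object)
  lab <- tibble::tibble(x = seq_along(object$labels),
                        label = object$labels[object$hclust$order])
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = lab$x, labels = lab$label) +
    ggplot2::labs(x = NULL,
                  y = if (object$rescaled) "rescaled height (0-25)" else "height",
                  title = sprintf("%s dendrogram", toupper(object$linkage))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (!is.null(cut)) {
    p <- p + ggplot2::geom_hline(yintercept = cut, linetype = "dashed",
                                 colour = "red")
  }
  p
}

# Segment coordinates of an hclust: leaves sit at 1..n in plotting order,
# every merge draws the usual n-shaped bracket at its height.
#' @noRd
dendro_segments <- function(d) {
  hc <- d$hclust
  n <- length(hc$labels)
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- node_y <- numeric(nrow(hc$merge))
  segs <- vector("list", nrow(hc$merge))
  pos <- function(m) {
    if (m < 0) c(leaf_x[-m], 0) else c(node_x[m], node_y[m])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[s, 1]); b <- pos(hc$merge[s, 2])
    h <- d$heights[s]
    node_x[s] <- mean(c(a[1], b[1])); node_y[s] <- h
    segs[[s]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h))
  }
  purrr::list_rbind(segs)
}

#' Heatmap of cross-marker concordance
#'
#' @param object A `marker_concordance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_concordance
#' @export
autoplot.marker_concordance <- function(object, ...) {
  df <- tibble::as_tibble(object$r, rownames = "method_a") |>
    tidyr::pivot_longer(-"method_a", names_to = "method_b", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$method_a, .data$method_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cluster-label concordance") +
    ggplot2::theme_minimal()
}

#' Bar plot of trait-by-multi-resistance correlations
#'
#' @param correlations Output of [trait_resistance_correlation()].
#' @return A ggplot object with significance flags above the bars.
#' @export
plot_trait_resistance <- function(correlations) {
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$trait, y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "Pearson r vs multi-resistance",
                  title = "Trait association with herbicide multi-resistance") +
    ggplot2::theme_minimal()
}
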