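#' Plot temporal cluster centroids
#'
#' One panel per cluster showing the centroid profile over the time grid
#' (z-score units when the clustering was standardized).
#'
#' @param object `cerna_clusters` object.
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot cerna_clusters
#' @export
autoplot.cerna_clusters <- function(object, ...) {
  centroids <- as_tibble(object$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint", values_to = "value") |>
    mutate(
      day = sample_day(.data$timepoint),
      cluster = paste0("cluster ", .data$cluster),
      n = NA_integer_
    )
  sizes <- dplyr::count(object$assignment, .data$cluster)
  centroids$n <- sizes$n[match(
    as.integer(stringr::str_remove(centroids$cluster, "cluster ")),
    sizes$cluster)]
  ggplot2::ggplot(centroids,
                  ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ paste0(.data$cluster, " (n=", .data$n, ")")) +
    ggplot2::labs(x = "day", y = if (object$standardized) "z-scored log2 expression"
                  else "log2 expression") +
    ggplot2::theme_bw()
}

#' Plot a ceRNA network
#'
#' Force-directed layout with competing and regulatory edges distinguished by
#' colour and node classes by shape/colour. The layout is seeded for
#' reproducibility.
#'
#' @param object `cerna_network` object.
#' @param seed layout seed.
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- tidy(object) |>
    dplyr::left_join(setNames(nodes[c("id", "x", "y")], c("from", "x0", "y0")),
                     by = "from") |>
    dplyr::left_join(setNames(nodes[c("id", "x", "y")], c("to", "x1", "y1")),
                     by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$edge_type),
      linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$type),
      shape = 21, size = 2) +
    ggplot2::scale_colour_manual(values = c(competing = "#7b3294",
                                            regulatory = "#e6ab02")) +
    ggplot2::labs(title = paste0(object$stage, " ceRNA network")) +
    ggplot2::theme_void()
}

#' Plot the degree distribution of a hub report
#'
#' @param object `hub_report` object.
#' @param ... unused.
#' @return ggplot object with the hub cutoff marked.
#' @method autoplot hub_report
#' @export
autoplot.hub_report <- function(object, ...) {
  d <- tidy(object)
  cutoff <- min(d$degree[d$is_hub])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, fill = .data$is_hub)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0) +
    ggplot2::geom_vline(xintercept = cutoff - 0.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#d95f02"),
                               name = "hub") +
    ggplot2::labs(x = "competing-edge degree", y = "RNA nodes",
                  title = paste0(object$stage, " network hubs")) +
    ggplot2::theme_bw()
}

#' Plot the two-group sample cut
#'
#' Samples in dendrogram order, coloured by their two-group assignment.
#'
#' @param object `sample_clustering` object.
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot sample_clustering
#' @export
autoplot.sample_clustering <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  d <- object$groups |>
    mutate(sample = factor(.data$sample, levels = ord),
           group = factor(.data$group))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = 1, fill = .data$group)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "sample clustering (two-group cut, dendrogram order)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano-style plot of the stage t-test
#'
#' @param de result tibble of [stage_de_ttest()].
#' @param alpha significance threshold drawn as a reference line.
#' @return ggplot object.
#' @export
plot_stage_de <- function(de, alpha = 0.05) {
  d <- mutate(de, delta = .data$mean_a - .data$mean_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#1b9e77")) +
    ggplot2::labs(x = "mean log2 difference (stage A - stage B)",
                  y = "-log10 p") +
    ggplot2::theme_bw()
}
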