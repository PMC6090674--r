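#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ceRNA network into an edge tibble
#' @param x `cerna_network` object.
#' @param ... unused.
#' @return tibble of edges with `from`, `to`, `edge_type` and, for competing
#'   edges, the pair statistics.
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) {
  dplyr::bind_rows(
    x$competing |>
      mutate(edge_type = "competing") |>
      dplyr::rename(from = "id_a", to = "id_b"),
    x$regulatory |>
      mutate(edge_type = "regulatory") |>
      dplyr::rename(from = "mirna_id", to = "target_id")
  ) |>
    select("from", "to", "edge_type", dplyr::everything())
}

#' @rdname tidy.cerna_network
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    stage = x$stage,
    n_rna = sum(x$nodes$type != "miRNA"),
    n_mirna = sum(x$nodes$type == "miRNA"),
    n_competing = nrow(x$competing),
    n_regulatory = nrow(x$regulatory)
  )
}

#' Tidy temporal cluster assignments
#' @param x `cerna_clusters` object.
#' @param ... unused.
#' @return the assignment tibble (`transcript_id`, `cluster`).
#' @method tidy cerna_clusters
#' @export
tidy.cerna_clusters <- function(x, ...) x$assignment

#' @rdname tidy.cerna_clusters
#' @method glance cerna_clusters
#' @export
glance.cerna_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignment), inertia = x$inertia,
         n_init = x$n_init, seed = x$seed)
}

#' Tidy a hub report into a per-node degree tibble
#' @param x `hub_report` object.
#' @param ... unused.
#' @return tibble `id`, `degree`, `is_hub`.
#' @method tidy hub_report
#' @export
tidy.hub_report <- function(x, ...) {
  mutate(x$degree, is_hub = .data$id %in% x$hub_set)
}

#' @rdname tidy.hub_report
#' @method glance hub_report
#' @export
glance.hub_report <- function(x, ...) {
  tibble(stage = x$stage, n_rna = nrow(x$degree),
         n_hubs = length(x$hub_set), fraction = x$fraction,
         tie_policy = x$tie_policy)
}

#' Tidy a sample clustering into its two-group cut
#' @param x `sample_clustering` object.
#' @param ... unused.
#' @return tibble `sample`, `group`.
#' @method tidy sample_clustering
#' @export
tidy.sample_clustering <- function(x, ...) x$groups

#' @rdname tidy.sample_clustering
#' @method glance sample_clustering
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble(n_samples = nrow(x$groups), distance = x$distance,
         linkage = x$linkage)
}
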