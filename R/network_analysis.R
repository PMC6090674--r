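#' Identify hub ceRNAs of a network
#'
#' Degree is counted over competing edges only, among RNA nodes only (miRNAs
#' are excluded). Nodes are ranked by (degree descending, id ascending) and
#' the top `ceiling(fraction * n)` are selected; nodes tied with the last
#' selected degree are all included (tie expansion), and the policy is
#' recorded.
#'
#' @param net `cerna_network` object.
#' @param fraction hub fraction (default 0.10, the top-10% rule).
#' @return object of class `hub_report`: list with `stage`, `degree` (tibble
#'   `id`, `degree`), `hub_set`, `fraction`, `tie_policy`.
#' @export
find_hubs <- function(net, fraction = 0.10) {
  rna <- dplyr::filter(net$nodes, .data$type != "miRNA")
  if (nrow(rna) == 0) abort("network has no RNA nodes")
  deg_tab <- table(factor(c(net$competing$id_a, net$competing$id_b),
                          levels = rna$id))
  degree <- tibble(id = names(deg_tab), degree = as.integer(deg_tab)) |>
    arrange(dplyr::desc(.data$degree), .data$id)
  n_hub <- ceiling(fraction * nrow(degree))
  cutoff <- degree$degree[n_hub]
  hub_set <- degree$id[degree$degree >= cutoff]
  structure(
    list(stage = net$stage, degree = degree, hub_set = hub_set,
         fraction = fraction, tie_policy = "expand_ties_at_cutoff"),
    class = "hub_report"
  )
}

#' @export
print.hub_report <- function(x, ...) {
  cat("<hub_report> stage:", x$stage, "-", length(x$hub_set), "hubs of",
      nrow(x$degree), "RNA nodes (fraction", x$fraction, ", tie policy",
      paste0(x$tie_policy, ")\n"))
  invisible(x)
}

#' Common and stage-specific hubs of two networks
#'
#' @param a,b `hub_report` objects over a shared id space.
#' @return tibble with columns `id` and `status` in `common`,
#'   `<stage_a>_specific`, `<stage_b>_specific`; the three groups are
#'   disjoint and cover both hub sets.
#' @export
compare_hubs <- function(a, b) {
  common <- intersect(a$hub_set, b$hub_set)
  only_a <- setdiff(a$hub_set, b$hub_set)
  only_b <- setdiff(b$hub_set, a$hub_set)
  dplyr::bind_rows(
    tibble(id = sort(common), status = "common"),
    tibble(id = sort(only_a), status = paste0(a$stage, "_specific")),
    tibble(id = sort(only_b), status = paste0(b$stage, "_specific"))
  )
}

#' Induced ceRNA subnetwork on a node set
#'
#' Keeps the competing edges with both endpoints in `node_set`, plus the
#' regulatory edges from miRNAs shared by at least one retained pair.
#'
#' @param net `cerna_network` object.
#' @param node_set character vector of RNA node ids.
#' @return `cerna_network` restricted to `node_set`.
#' @export
extract_subnetwork <- function(net, node_set) {
  if (length(node_set) == 0) abort("node_set must be non-empty")
  competing <- dplyr::filter(net$competing,
                             .data$id_a %in% node_set, .data$id_b %in% node_set)
  assemble_network(
    mutate(competing, accepted = TRUE),
    mutate(net$regulatory,
           target_class = net$nodes$type[match(.data$target_id, net$nodes$id)]),
    stage_label = net$stage
  )
}

#' Randomization (permutation) test for gene-set enrichment
#'
#' Draws `n_perm` uniform subsets of size `|query|` from the background and
#' compares their overlap with the annotated set to the observed overlap.
#' The p-value uses the add-one estimator
#' `(1 + #{overlap >= observed}) / (1 + n_perm)`, so it is always positive.
#' The exact hypergeometric tail is reported alongside for reference.
#'
#' @param query,annotated,background character id sets; `query` and
#'   `annotated` must be subsets of `background`.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for reproducible draws.
#' @return one-row tibble: `overlap`, `expected`, `p_perm`, `p_hyper`,
#'   `n_perm`, `seed`.
#' @export
randomization_enrichment <- function(query, annotated, background,
                                     n_perm = 10000, seed = NULL) {
  query <- unique(query); annotated <- unique(annotated)
  background <- unique(background)
  if (length(setdiff(query, background))) abort("query must be a subset of background")
  if (length(setdiff(annotated, background))) abort("annotated must be a subset of background")
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  observed <- length(intersect(query, annotated))
  hits <- background %in% annotated
  n_q <- length(query)
  exceed <- sum(vapply(seq_len(n_perm), function(i) {
    sum(hits[sample.int(length(background), n_q)]) >= observed
  }, numeric(1)))
  tibble(
    overlap = observed,
    expected = n_q * length(annotated) / length(background),
    p_perm = (1 + exceed) / (1 + n_perm),
    p_hyper = stats::phyper(observed - 1, length(annotated),
                            length(background) - length(annotated),
                            n_q, lower.tail = FALSE),
    n_perm = n_perm,
    seed = seed %||% NA_integer_
  )
}

#' Hypergeometric gene-set enrichment with BH FDR
#'
#' Upper-tail hypergeometric p-value of the overlap between one query set and
#' each annotated set, Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param query character id set.
#' @param annotated_sets named list of character id sets.
#' @param background character id set containing `query` and every annotated
#'   set.
#' @param fdr_max significance threshold on the adjusted value.
#' @return tibble: `set_name`, `overlap`, `expected`, `p_hyper`, `fdr`,
#'   `significant`, ordered as the input sets.
#' @export
hypergeom_set_enrichment <- function(query, annotated_sets, background,
                                     fdr_max = 0.05) {
  background <- unique(background)
  if (length(background) == 0) abort("background must be non-empty")
  query <- unique(query)
  if (length(setdiff(query, background))) abort("query must be a subset of background")
  res <- purrr::imap(annotated_sets, function(set, nm) {
    set <- unique(set)
    if (length(setdiff(set, background))) {
      abort(paste0("annotated set '", nm, "' is not a subset of background"))
    }
    overlap <- length(intersect(query, set))
    tibble(
      set_name = nm,
      overlap = overlap,
      expected = length(query) * length(set) / length(background),
      p_hyper = stats::phyper(overlap - 1, length(set),
                              length(background) - length(set),
                              length(query), lower.tail = FALSE)
    )
  }) |> purrr::list_rbind()
  res |>
    mutate(fdr = stats::p.adjust(.data$p_hyper, method = "BH"),
           significant = .data$fdr < fdr_max)
}

#' Partition stage-network competing edges around a focus set
#'
#' Restricts competing edges to those with at least one endpoint in `focus`
#' and partitions them into common, growth-only and senescence-only edges.
#'
#' @param growth,senescence `cerna_network` objects over a shared id space.
#' @param focus character vector of focal transcript ids.
#' @return tibble with columns `id_a`, `id_b`, `status` in `common`,
#'   `<growth stage>_only`, `<senescence stage>_only`.
#' @export
compare_stage_edges <- function(growth, senescence, focus) {
  edge_keys <- function(net) {
    e <- net$competing
    keep <- e$id_a %in% focus | e$id_b %in% focus
    a <- pmin(e$id_a[keep], e$id_b[keep])
    b <- pmax(e$id_a[keep], e$id_b[keep])
    unique(paste(a, b, sep = "\t"))
  }
  kg <- edge_keys(growth); ks <- edge_keys(senescence)
  build <- function(keys, status) {
    if (length(keys) == 0) {
      return(tibble(id_a = character(), id_b = character(), status = character()))
    }
    parts <- stringr::str_split_fixed(keys, "\t", 2)
    tibble(id_a = parts[, 1], id_b = parts[, 2], status = status)
  }
  dplyr::bind_rows(
    build(sort(intersect(kg, ks)), "common"),
    build(sort(setdiff(kg, ks)), paste0(growth$stage, "_only")),
    build(sort(setdiff(ks, kg)), paste0(senescence$stage, "_only"))
  )
}
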