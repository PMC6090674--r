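#' Hypergeometric test for shared miRNA regulators
#'
#' Upper-tail probability that two transcripts with `K_a` and `K_b` miRNA
#' regulators drawn from a universe of `N` expressed miRNAs share at least `k`
#' of them: `P(X >= k)` with `X ~ Hypergeometric(N, K_a, K_b)`. The test is
#' symmetric in `K_a` and `K_b`, equals 1 at `k = 0`, and is non-increasing
#' in `k`.
#'
#' @param k observed number of shared miRNAs.
#' @param K_a,K_b miRNA-regulator set sizes of the two transcripts.
#' @param N size of the miRNA universe.
#' @return p-value vector (arguments recycle as usual).
#' @export
hypergeom_shared_test <- function(k, K_a, K_b, N) {
  n <- max(length(k), length(K_a), length(K_b), length(N))
  k <- rep_len(k, n); K_a <- rep_len(K_a, n)
  K_b <- rep_len(K_b, n); N <- rep_len(N, n)
  if (any(N < 1)) abort("N must be >= 1")
  if (any(K_a > N | K_b > N)) abort("K_a and K_b must not exceed N")
  if (any(k < 0 | k > pmin(K_a, K_b))) abort("k must lie in [0, min(K_a, K_b)]")
  stats::phyper(k - 1, K_a, N - K_a, K_b, lower.tail = FALSE)
}

#' Call ceRNA pairs by shared-miRNA significance and co-expression
#'
#' Two-criterion procedure: an unordered transcript pair sharing at least
#' `min_shared` miRNA regulators is accepted as a ceRNA interaction when the
#' shared-miRNA hypergeometric p-value satisfies `p_hyper < p_hyper_max` and
#' its temporal Pearson correlation satisfies `r > r_min` and
#' `p_corr < p_corr_max` (all strict). Candidate pairs are enumerated through
#' an inverted miRNA-to-targets index, which yields exactly the pairs sharing
#' at least one miRNA.
#'
#' The hypergeometric universe N is the number of distinct miRNAs in `table`
#' (i.e. expressed miRNAs with at least one surviving edge) unless
#' `mirna_universe` supplies a larger explicit universe.
#'
#' @param table restricted target-edge tibble (see [restrict_to_expressed()]).
#' @param expr log2-scale expression tibble covering every target in `table`
#'   (replicates averaged).
#' @param p_hyper_max,r_min,p_corr_max,min_shared acceptance thresholds.
#' @param mirna_universe optional character vector overriding the universe.
#' @param parent_map optional tibble (`junction_id`, `parent_gene`) used to
#'   flag pairs between a circRNA and its own parent gene.
#' @param keep_rejected return all candidate pairs with an `accepted` flag
#'   instead of only the accepted ones.
#' @return tibble of pairs, lexicographically ordered by (`id_a`, `id_b`),
#'   with columns `id_a`, `id_b`, `class_a`, `class_b`, `k_shared`, `K_a`,
#'   `K_b`, `N_universe`, `p_hyper`, `r`, `p_corr`, `accepted` and (when
#'   `parent_map` is given) `same_parent`.
#' @export
call_cerna_pairs <- function(table, expr,
                             p_hyper_max = 0.05, r_min = 0.5,
                             p_corr_max = 0.05, min_shared = 1,
                             mirna_universe = NULL, parent_map = NULL,
                             keep_rejected = FALSE) {
  sc <- expr_scale(expr)
  if (!is.null(sc) && sc != "log2p1") {
    abort("call_cerna_pairs() expects log2-scale expression")
  }
  missing_ids <- setdiff(unique(table$target_id), expr$transcript_id)
  if (length(missing_ids)) {
    abort(paste0("transcript(s) in target table absent from expression: ",
                 paste(utils::head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) " ..."))
  }
  N <- if (is.null(mirna_universe)) {
    dplyr::n_distinct(table$mirna_id)
  } else {
    length(unique(mirna_universe))
  }

  edges <- distinct(table, .data$mirna_id, .data$target_id)
  k_size <- edges |> dplyr::count(.data$target_id, name = "K")
  classes <- distinct(table, .data$target_id, .data$target_class)

  pairs <- dplyr::inner_join(edges, edges, by = "mirna_id",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$target_id.x < .data$target_id.y) |>
    dplyr::count(id_a = .data$target_id.x, id_b = .data$target_id.y,
                 name = "k_shared") |>
    dplyr::filter(.data$k_shared >= min_shared)

  if (nrow(pairs) == 0) {
    out <- tibble(id_a = character(), id_b = character(),
                  class_a = character(), class_b = character(),
                  k_shared = integer(), K_a = integer(), K_b = integer(),
                  N_universe = integer(), p_hyper = numeric(), r = numeric(),
                  p_corr = numeric(), accepted = logical())
    return(out)
  }

  pairs <- pairs |>
    dplyr::left_join(setNames(k_size, c("id_a", "K_a")), by = "id_a") |>
    dplyr::left_join(setNames(k_size, c("id_b", "K_b")), by = "id_b") |>
    dplyr::left_join(setNames(classes, c("id_a", "class_a")), by = "id_a") |>
    dplyr::left_join(setNames(classes, c("id_b", "class_b")), by = "id_b") |>
    mutate(
      N_universe = N,
      p_hyper = hypergeom_shared_test(.data$k_shared, .data$K_a, .data$K_b, N)
    )

  vals <- expr_values(expr)
  vc <- vals - rowMeans(vals)
  norms <- sqrt(rowSums(vc^2))
  ia <- match(pairs$id_a, rownames(vals))
  ib <- match(pairs$id_b, rownames(vals))
  den <- norms[ia] * norms[ib]
  r <- unname(ifelse(den > 0,
                     rowSums(vc[ia, , drop = FALSE] * vc[ib, , drop = FALSE]) / den,
                     NA_real_))
  n_obs <- ncol(vals)
  pairs <- pairs |>
    mutate(
      r = r,
      p_corr = ifelse(is.na(r), NA_real_, pearson_p(r, n_obs)),
      accepted = .data$p_hyper < p_hyper_max &
        !is.na(r) & r > r_min & .data$p_corr < p_corr_max
    )
  if (!is.null(parent_map)) {
    key_ab <- paste(pairs$id_a, pairs$id_b)
    key_ba <- paste(pairs$id_b, pairs$id_a)
    parent_keys <- paste(parent_map$junction_id, parent_map$parent_gene)
    pairs$same_parent <- key_ab %in% parent_keys | key_ba %in% parent_keys
  }
  pairs <- pairs |>
    select("id_a", "id_b", "class_a", "class_b", "k_shared", "K_a", "K_b",
           "N_universe", "p_hyper", "r", "p_corr", "accepted",
           dplyr::any_of("same_parent")) |>
    arrange(.data$id_a, .data$id_b)
  if (keep_rejected) pairs else dplyr::filter(pairs, .data$accepted)
}

#' Assemble a ceRNA network from accepted pairs
#'
#' Nodes are the pair endpoints (RNA nodes with their classes) plus every
#' miRNA shared by at least one accepted pair; competing edges are the
#' accepted pairs and regulatory edges are the target-table edges from those
#' shared miRNAs to the RNA nodes.
#'
#' @param pairs accepted pair tibble from [call_cerna_pairs()].
#' @param table the target-edge tibble the pairs were called on.
#' @param stage_label `"global"`, `"growth"` or `"senescence"`.
#' @return object of class `cerna_network`: list with `nodes`, `competing`,
#'   `regulatory`, `stage`.
#' @export
assemble_network <- function(pairs, table, stage_label = "global") {
  if ("accepted" %in% names(pairs)) {
    pairs <- dplyr::filter(pairs, .data$accepted)
  }
  rna_nodes <- dplyr::bind_rows(
    tibble(id = pairs$id_a, type = pairs$class_a),
    tibble(id = pairs$id_b, type = pairs$class_b)
  ) |> distinct() |> arrange(.data$id)

  edges <- distinct(table, .data$mirna_id, .data$target_id)
  mirnas_by_target <- split(edges$mirna_id, edges$target_id)
  shared <- sort(unique(as.character(unlist(purrr::map2(
    pairs$id_a, pairs$id_b,
    function(a, b) intersect(mirnas_by_target[[a]], mirnas_by_target[[b]])
  )))))

  regulatory <- edges |>
    dplyr::filter(.data$mirna_id %in% shared,
                  .data$target_id %in% rna_nodes$id) |>
    arrange(.data$mirna_id, .data$target_id)

  nodes <- dplyr::bind_rows(rna_nodes, tibble(id = shared, type = "miRNA"))
  structure(
    list(nodes = nodes,
         competing = select(pairs, -dplyr::any_of("accepted")),
         regulatory = regulatory,
         stage = stage_label),
    class = "cerna_network"
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  n_rna <- sum(x$nodes$type != "miRNA")
  cat("<cerna_network> stage:", x$stage, "\n")
  cat("  ", n_rna, " RNA nodes, ", sum(x$nodes$type == "miRNA"), " miRNAs, ",
      nrow(x$competing), " competing edges, ", nrow(x$regulatory),
      " regulatory edges\n", sep = "")
  invisible(x)
}

#' Stage-restricted ceRNA networks
#'
#' Re-runs the pair-calling per development stage using only that stage's
#' expression columns; target sets, and hence the shared-miRNA test, are
#' stage-independent. The hypergeometric universe is kept global by default.
#'
#' @param table restricted target-edge tibble.
#' @param expr log2-scale expression tibble (replicates averaged).
#' @param partition a [default_stage_partition()] result, or any named list of
#'   sample-column sets with at least 3 samples each.
#' @param ... thresholds forwarded to [call_cerna_pairs()].
#' @return named list of `cerna_network` objects, one per stage.
#' @export
stage_networks <- function(table, expr, partition, ...) {
  purrr::imap(partition, function(samples, stage) {
    if (length(samples) < 3) {
      abort(paste0("stage '", stage, "' has fewer than 3 samples"))
    }
    sub <- expr[c(intersect(.annot_cols, names(expr)), samples)]
    sub <- set_expr_scale(sub, expr_scale(expr))
    pairs <- call_cerna_pairs(table, sub, ...)
    assemble_network(pairs, table, stage_label = stage)
  })
}

#' Convert a ceRNA network to igraph
#' @param net `cerna_network` object.
#' @return undirected igraph graph; vertices carry `type`, edges `edge_type`.
#' @export
as_igraph <- function(net) {
  edges <- dplyr::bind_rows(
    tibble(from = net$competing$id_a, to = net$competing$id_b,
           edge_type = "competing"),
    tibble(from = net$regulatory$mirna_id, to = net$regulatory$target_id,
           edge_type = "regulatory")
  )
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a ceRNA network as TSV node/edge tables and GraphML
#'
#' @param net `cerna_network` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the stage label.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, dir, prefix = net$stage) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_nodes.tsv", "_edges.tsv", ".graphml")))
  readr::write_tsv(net$nodes, paths[1], progress = FALSE)
  edges <- dplyr::bind_rows(
    mutate(select(net$competing, from = "id_a", to = "id_b"),
           edge_type = "competing"),
    mutate(select(net$regulatory, from = "mirna_id", to = "target_id"),
           edge_type = "regulatory")
  )
  readr::write_tsv(edges, paths[2], progress = FALSE)
  igraph::write_graph(as_igraph(net), paths[3], format = "graphml")
  invisible(paths)
}
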