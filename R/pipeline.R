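#' Configuration for an end-to-end pipeline run
#'
#' Collects every threshold of the analysis under its named default: junction
#' support, abundance cutoffs, reproducibility and ceRNA-pair thresholds, hub
#' fraction, number of temporal clusters and permutation count. Inputs come
#' either from a fixture-bundle directory (`input_dir`) or from the synthetic
#' generator (`simulate`), in which case the bundle is written under the
#' output directory first so the run always consumes files.
#'
#' @param out_dir output directory for all artifacts.
#' @param input_dir directory holding a fixture bundle (see
#'   [write_fixture_bundle()]); mutually exclusive with `simulate`.
#' @param simulate a [sim_config()] describing the dataset to generate.
#' @param min_junction_reads junction-read support threshold.
#' @param junction_support_mode `"per_sample"` or `"summed"`.
#' @param r_repro_min,p_repro_max replicate-reproducibility thresholds.
#' @param p_hyper_max,r_min,p_corr_max,min_shared ceRNA-pair thresholds.
#' @param hub_fraction top-degree fraction defining hubs.
#' @param k number of temporal clusters.
#' @param n_perm permutations for the randomization enrichment test.
#' @param stage_mode `"fixed_days"` (growth Day4-18 vs senescence Day20-30)
#'   or `"from_sample_clustering"` (two-group cut of the sample dendrogram).
#' @param de_alpha significance threshold of the stage t-test.
#' @param seed integer seed for all stochastic stages.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       input_dir = NULL,
                       simulate = NULL,
                       min_junction_reads = 2,
                       junction_support_mode = "per_sample",
                       r_repro_min = 0.5, p_repro_max = 0.05,
                       p_hyper_max = 0.05, r_min = 0.5, p_corr_max = 0.05,
                       min_shared = 1,
                       hub_fraction = 0.10,
                       k = 6,
                       n_perm = 1000,
                       stage_mode = c("fixed_days", "from_sample_clustering"),
                       de_alpha = 0.05,
                       seed = 1) {
  stage_mode <- match.arg(stage_mode)
  if (is.null(input_dir) && is.null(simulate)) {
    abort("run_config() needs either input_dir or a simulate block",
          class = "cernaforge_config_error")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  probs <- c(p_repro_max, p_hyper_max, p_corr_max, de_alpha)
  if (any(probs < 0 | probs > 1) || r_min < -1 || r_min > 1 ||
      hub_fraction <= 0 || hub_fraction > 1 || min_junction_reads < 0 ||
      k < 1 || n_perm < 100) {
    abort("threshold out of range", class = "cernaforge_config_error")
  }
  structure(as.list(environment()), class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of [run_config()] fields (a `simulate:` block is
#'   passed to [sim_config()]).
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Run the full ceRNA-network analysis
#'
#' Executes annotation, expression, interactions, ceRNA calling (global and
#' per stage), clustering and network analysis in order, writes every
#' intermediate artifact under the configured output directory, and returns
#' the in-memory results together with a run manifest (configuration, seed,
#' per-stage record counts).
#'
#' @param config a [run_config()].
#' @return object of class `cernaforge_run`: list with `results`, `manifest`,
#'   `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }

  ## ---- inputs ---------------------------------------------------------------
  input_dir <- config$input_dir
  if (is.null(input_dir)) {
    input_dir <- file.path(config$out_dir, "input")
    stage("simulate", write_fixture_bundle(input_dir, config$simulate))
  }
  bundle <- stage("ingest", read_fixture_bundle(input_dir))

  ## ---- annotation -----------------------------------------------------------
  ann <- stage("annotation", {
    calls <- purrr::imap(bundle$caller_paths, read_junction_calls)
    merged <- merge_junction_calls(calls, min_reads = config$min_junction_reads,
                                   mode = config$junction_support_mode)
    classified <- classify_circ_junctions(merged, bundle$gene_models)
    lnc_candidates <- filter_lncrna_candidates(bundle$lncrna_candidates)
    list(junctions = classified, lnc_candidates = lnc_candidates)
  })

  ## ---- expression -----------------------------------------------------------
  expression <- stage("expression", {
    totals <- bundle$totals
    norm <- list(
      mRNA = fpkm(bundle$counts$mRNA, bundle$lengths, totals),
      lncRNA = fpkm(bundle$counts$lncRNA, bundle$lengths, totals),
      circRNA = junction_counts_matrix(ann$junctions),
      miRNA = rpm(bundle$counts$miRNA, totals)
    )
    norm$circRNA_rpm <- rpm(norm$circRNA, totals)

    abundance <- abundance_filter(norm[c("mRNA", "lncRNA", "circRNA", "miRNA")])

    logged <- list(
      mRNA = log2p1(norm$mRNA), lncRNA = log2p1(norm$lncRNA),
      circRNA = log2p1(norm$circRNA_rpm), miRNA = log2p1(norm$miRNA)
    )
    has_reps <- anyDuplicated(sample_timepoint(sample_cols(logged$mRNA))) > 0
    repro <- if (has_reps) {
      purrr::map(logged, function(x) {
        reps <- split_replicates(x)
        reproducibility_filter(reps[[1]], reps[[2]],
                               r_min = config$r_repro_min,
                               p_max = config$p_repro_max)
      }) |> purrr::list_rbind(names_to = "rna_class")
    } else {
      NULL
    }
    retained <- abundance |>
      dplyr::filter(.data$retained) |>
      dplyr::pull("transcript_id")
    if (!is.null(repro)) {
      retained <- intersect(retained,
                            repro$transcript_id[repro$retained])
    }
    averaged <- purrr::map(logged, average_replicates)
    expr_all <- purrr::list_rbind(purrr::map(averaged, identity)) |>
      set_expr_scale("log2p1")
    expr_kept <- dplyr::filter(expr_all, .data$transcript_id %in% retained) |>
      set_expr_scale("log2p1")
    list(normalized = norm, abundance = abundance, reproducibility = repro,
         expressed_ids = retained, expr = expr_kept, expr_all = expr_all)
  })

  ## ---- interactions ---------------------------------------------------------
  interactions <- stage("interactions", {
    tables <- purrr::imap(bundle$predictor_paths, read_predictions)
    merged <- union_merge(tables)
    expressed_mirnas <- intersect(
      expression$expressed_ids,
      expression$normalized$miRNA$transcript_id
    )
    expressed_targets <- setdiff(expression$expressed_ids, expressed_mirnas)
    restricted <- restrict_to_expressed(merged, expressed_mirnas,
                                        expressed_targets)
    list(merged = merged, restricted = restricted)
  })

  ## ---- ceRNA calling --------------------------------------------------------
  parent_map <- ann$junctions |>
    dplyr::filter(.data$circ_class == "exonic") |>
    select(junction_id = "junction_id", parent_gene = "parent_genes")
  rna_expr <- expression$expr |>
    dplyr::filter(.data$rna_class != "miRNA") |>
    set_expr_scale("log2p1")
  cerna <- stage("cerna", {
    pairs <- call_cerna_pairs(
      interactions$restricted, rna_expr,
      p_hyper_max = config$p_hyper_max, r_min = config$r_min,
      p_corr_max = config$p_corr_max, min_shared = config$min_shared,
      parent_map = parent_map, keep_rejected = TRUE
    )
    accepted <- dplyr::filter(pairs, .data$accepted)
    global <- assemble_network(accepted, interactions$restricted, "global")
    list(pairs = pairs, accepted = accepted, global = global)
  })

  ## ---- stages and clustering ------------------------------------------------
  clustering <- stage("clustering", {
    samples_cl <- cluster_samples(expression$expr)
    partition <- if (config$stage_mode == "fixed_days") {
      default_stage_partition(sample_cols(expression$expr))
    } else {
      grp <- split(samples_cl$groups$sample, samples_cl$groups$group)
      # earlier-day group is the growth stage
      first_growth <- which.min(purrr::map_dbl(grp, ~ min(sample_day(.x))))
      structure(list(growth = grp[[first_growth]],
                     senescence = grp[[-first_growth + 3L]]),
                class = c("stage_partition", "list"))
    }
    node_ids <- cerna$global$nodes$id[cerna$global$nodes$type != "miRNA"]
    cerna_expr <- dplyr::filter(expression$expr,
                                .data$transcript_id %in% node_ids) |>
      set_expr_scale("log2p1")
    clusters <- if (nrow(cerna_expr) >= config$k) {
      cluster_cernas(cerna_expr, k = config$k, seed = config$seed)
    } else {
      NULL
    }
    list(samples = samples_cl, partition = partition, clusters = clusters)
  })

  stages <- stage("stage_networks", {
    stage_networks(interactions$restricted, rna_expr, clustering$partition,
                   p_hyper_max = config$p_hyper_max, r_min = config$r_min,
                   p_corr_max = config$p_corr_max,
                   min_shared = config$min_shared)
  })

  ## ---- differential expression ----------------------------------------------
  de <- stage("differential_expression", {
    stage_de_ttest(expression$expr, clustering$partition$growth,
                   clustering$partition$senescence, alpha = config$de_alpha)
  })

  ## ---- network analysis -----------------------------------------------------
  network_analysis <- stage("network_analysis", {
    hubs <- purrr::map(c(list(global = cerna$global), stages), function(n) {
      if (sum(n$nodes$type != "miRNA") > 0) find_hubs(n, config$hub_fraction)
    })
    hub_comparison <- if (!is.null(hubs$growth) && !is.null(hubs$senescence)) {
      compare_hubs(hubs$growth, hubs$senescence)
    } else {
      tibble(id = character(), status = character())
    }
    common_ids <- hub_comparison$id[hub_comparison$status == "common"]
    common_sub <- if (length(common_ids)) {
      extract_subnetwork(cerna$global, common_ids)
    }
    background <- expression$normalized$mRNA$transcript_id
    query <- intersect(cerna$global$nodes$id, background)
    set.seed(config$seed)
    enrichment <- purrr::imap(bundle$gene_lists, function(set, nm) {
      mutate(randomization_enrichment(query, intersect(set, background),
                                      background, n_perm = config$n_perm),
             set_name = nm, .before = 1)
    }) |> purrr::list_rbind()
    enrichment_hyper <- hypergeom_set_enrichment(
      query, purrr::map(bundle$gene_lists, intersect, background), background
    )
    list(hubs = hubs, hub_comparison = hub_comparison,
         common_subnetwork = common_sub,
         enrichment_perm = enrichment, enrichment_hyper = enrichment_hyper)
  })

  ## ---- parent-gene co-expression --------------------------------------------
  parent_coexp <- stage("parent_coexpression", {
    gene_expr <- average_replicates(log2p1(expression$normalized$mRNA))
    circ_expr <- average_replicates(log2p1(expression$normalized$circRNA_rpm))
    parent_coexpression(ann$junctions, circ_expr, gene_expr,
                        r_min = config$r_min, p_max = config$p_corr_max)
  })

  results <- list(
    annotation = ann, expression = expression, interactions = interactions,
    cerna = cerna, clustering = clustering, stage_nets = stages, de = de,
    network_analysis = network_analysis, parent_coexpression = parent_coexp
  )
  paths <- stage("write_outputs", write_run_outputs(config, results))
  manifest <- build_manifest(config, results, paths)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(results = results, manifest = manifest, paths = paths),
            class = "cernaforge_run")
}

# per-sample junction support as a raw-count expression table
junction_counts_matrix <- function(junctions) {
  samples <- setdiff(names(junctions),
                     c("junction_id", "chrom", "start", "end", "strand",
                       "callers", "max_support", "circ_class", "parent_genes"))
  dplyr::bind_cols(
    tibble(transcript_id = junctions$junction_id, rna_class = "circRNA"),
    junctions[samples]
  ) |> expression_matrix("raw_count")
}

# split an expression table into per-replicate tables (columns Day*_R<i>)
split_replicates <- function(x) {
  sc <- sample_cols(x)
  rep_tag <- stringr::str_match(sc, "_R([0-9]+)$")[, 2]
  reps <- sort(unique(rep_tag))
  purrr::map(reps, function(r) {
    cols <- sc[rep_tag == r]
    out <- x[c(intersect(.annot_cols, names(x)), cols)]
    names(out) <- c(intersect(.annot_cols, names(x)), sample_timepoint(cols))
    set_expr_scale(out, expr_scale(x))
  })
}

write_run_outputs <- function(config, res) {
  out <- config$out_dir
  p <- function(f) file.path(out, f)
  readr::write_tsv(res$cerna$pairs, p("cerna_pairs.tsv"), progress = FALSE)
  readr::write_tsv(res$annotation$junctions, p("junctions_classified.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$expression$abundance, p("abundance_filter.tsv"),
                   progress = FALSE)
  if (!is.null(res$expression$reproducibility)) {
    readr::write_tsv(res$expression$reproducibility,
                     p("reproducibility_filter.tsv"), progress = FALSE)
  }
  readr::write_tsv(res$de, p("stage_de.tsv"), progress = FALSE)
  readr::write_tsv(res$network_analysis$hub_comparison, p("hub_comparison.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$network_analysis$enrichment_perm,
                   p("enrichment_randomization.tsv"), progress = FALSE)
  readr::write_tsv(res$network_analysis$enrichment_hyper,
                   p("enrichment_hypergeometric.tsv"), progress = FALSE)
  if (!is.null(res$clustering$clusters)) {
    readr::write_tsv(res$clustering$clusters$assignment,
                     p("cerna_clusters.tsv"), progress = FALSE)
    utils::write.table(res$clustering$clusters$centroids,
                       p("cluster_centroids.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  write_dendrogram(res$clustering$samples, p("sample_dendrogram.nwk"))
  net_dir <- p("networks")
  for (net in c(list(res$cerna$global), res$stage_nets)) {
    write_network(net, net_dir)
  }
  sort(list.files(out, recursive = TRUE, full.names = TRUE))
}

build_manifest <- function(config, res, paths) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  cfg <- drop_null(unclass(config))
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  list(
    package = "cernaforge",
    version = as.character(utils::packageVersion("cernaforge")),
    seed = config$seed,
    config = cfg,
    counts = list(
      junctions_retained = nrow(res$annotation$junctions),
      transcripts_expressed = length(res$expression$expressed_ids),
      target_edges_merged = nrow(res$interactions$merged),
      target_edges_restricted = nrow(res$interactions$restricted),
      candidate_pairs = nrow(res$cerna$pairs),
      accepted_pairs = nrow(res$cerna$accepted),
      network_nodes = nrow(res$cerna$global$nodes),
      stage_edges = purrr::map(res$stage_nets, ~ nrow(.x$competing)),
      de_significant = sum(res$de$significant),
      clusters = if (!is.null(res$clustering$clusters)) res$clustering$clusters$k else 0L
    ),
    output_md5 = as.list(tools::md5sum(paths))
  )
}

#' @export
print.cernaforge_run <- function(x, ...) {
  cat("<cernaforge_run> seed", x$manifest$seed, "\n")
  utils::str(x$manifest$counts, give.attr = FALSE)
  invisible(x)
}
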