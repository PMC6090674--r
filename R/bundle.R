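#' Write a simulated dataset as a fixture bundle on disk
#'
#' Emits every input file the pipeline consumes — GFF3 gene models, candidate
#' transcript FASTA, per-class raw count TSVs with transcript lengths and
#' library totals, two partially overlapping predictor TSVs, two caller
#' junction BEDs, annotation gene lists — plus the ground-truth JSON, the
#' generating configuration as YAML, and a manifest with MD5 checksums.
#' Identical configurations (same seed) produce byte-identical bundles.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @param dataset optionally, an already-simulated dataset for this config.
#' @return invisibly, the manifest tibble (`file`, `bytes`, `md5`).
#' @export
write_fixture_bundle <- function(outdir, config = sim_config(),
                                 dataset = NULL) {
  ds <- dataset %||% simulate_dataset(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  write_gene_models_gff3(ds$genome$genes, ds$genome$chrom_lengths, p("genome.gff3"))

  seqs <- Biostrings::DNAStringSet(setNames(ds$lncrna_candidates$sequence,
                                            ds$lncrna_candidates$transcript_id))
  Biostrings::writeXStringSet(seqs, p("lncrna_candidates.fa"))
  readr::write_tsv(ds$lncrna_candidates[c("transcript_id", "class_code")],
                   p("lncrna_candidates.tsv"), progress = FALSE)

  for (cls in names(ds$counts)) {
    readr::write_tsv(select(ds$counts[[cls]], -"rna_class"),
                     p(paste0("counts_", tolower(cls), ".tsv")), progress = FALSE)
  }
  readr::write_tsv(tibble(transcript_id = names(ds$lengths),
                          length = unname(ds$lengths)),
                   p("transcript_lengths.tsv"), progress = FALSE)
  readr::write_tsv(tibble(sample = names(ds$totals), total = unname(ds$totals)),
                   p("library_totals.tsv"), progress = FALSE)

  for (nm in names(ds$predictor_tables)) {
    readr::write_tsv(
      ds$predictor_tables[[nm]][c("mirna_id", "target_id", "target_class")],
      p(paste0("targets_", nm, ".tsv")), progress = FALSE)
  }
  for (nm in names(ds$caller_tables)) {
    readr::write_tsv(ds$caller_tables[[nm]],
                     p(paste0("junctions_", nm, ".bed")),
                     col_names = FALSE, progress = FALSE)
  }
  writeLines(ds$gene_lists$TF, p("tf_genes.txt"))
  writeLines(ds$gene_lists$leaf_associated, p("leaf_genes.txt"))

  write_ground_truth(ds$ground_truth, p("ground_truth.json"))
  yaml::write_yaml(unclass(config), p("sim_config.yaml"))

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- tibble(
    file = files,
    bytes = file.size(file.path(outdir, files)),
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# gene/mRNA/exon features; internal 0-based half-open -> GFF3 1-based closed
write_gene_models_gff3 <- function(genes, chrom_lengths, path) {
  feat <- purrr::pmap(genes, function(gene_id, chrom, strand, start, end,
                                      biotype, exons, ...) {
    tx_id <- paste0(gene_id, ".1")
    dplyr::bind_rows(
      tibble(chrom = chrom, start = start + 1L, end = end, strand = strand,
             type = "gene", ID = gene_id, Parent = NA_character_,
             biotype = biotype),
      tibble(chrom = chrom, start = start + 1L, end = end, strand = strand,
             type = "mRNA", ID = tx_id, Parent = gene_id,
             biotype = NA_character_),
      tibble(chrom = chrom, start = exons$start + 1L, end = exons$end,
             strand = strand, type = "exon",
             ID = paste0(tx_id, ".exon", seq_len(nrow(exons))),
             Parent = tx_id, biotype = NA_character_)
    )
  }) |> purrr::list_rbind()
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand
  )
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(feat$Parent), "", feat$Parent)
  S4Vectors::mcols(gr)$biotype <- feat$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write / read planted ground truth as JSON
#'
#' @param gt ground-truth list from [simulate_dataset()].
#' @param path JSON file.
#' @return `read_ground_truth()` returns the ground-truth list with tibbles
#'   restored; `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$planted_pairs <- as_tibble(x$planted_pairs)
  x$cluster_assignment <- as_tibble(x$cluster_assignment)
  x$stage_labels <- as_tibble(x$stage_labels)
  x$circ_classes <- as_tibble(x$circ_classes)
  x$annotated_gene_sets <- purrr::map(x$annotated_gene_sets, as.character)
  x$lncrna_candidates_retained <- as.character(x$lncrna_candidates_retained)
  x$low_support_junction <- as.character(x$low_support_junction)
  x
}

#' Read a fixture bundle back from disk
#'
#' Inverse of [write_fixture_bundle()]: returns the tables the pipeline
#' consumes, read from their on-disk formats.
#'
#' @param dir bundle directory.
#' @return list with `counts` (per-class raw-count expression tibbles),
#'   `lengths`, `totals`, `gene_models`, `predictor_paths`, `caller_paths`,
#'   `gene_lists`, `lncrna_candidates`, `ground_truth` (when present).
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  read_counts <- function(f, cls) {
    x <- readr::read_tsv(p(f), col_types = readr::cols(
      transcript_id = readr::col_character(), .default = readr::col_double()
    ), progress = FALSE)
    expression_matrix(mutate(x, rna_class = cls, .after = "transcript_id"),
                      "raw_count")
  }
  lengths_tbl <- readr::read_tsv(p("transcript_lengths.tsv"),
                                 col_types = "cd", progress = FALSE)
  totals_tbl <- readr::read_tsv(p("library_totals.tsv"),
                                col_types = "cd", progress = FALSE)
  cand <- readr::read_tsv(p("lncrna_candidates.tsv"), col_types = "cc",
                          progress = FALSE)
  seqs <- Biostrings::readDNAStringSet(p("lncrna_candidates.fa"))
  cand$sequence <- as.character(seqs[cand$transcript_id])

  gt_path <- p("ground_truth.json")
  list(
    counts = list(
      mRNA = read_counts("counts_mrna.tsv", "mRNA"),
      lncRNA = read_counts("counts_lncrna.tsv", "lncRNA"),
      circRNA = read_counts("counts_circrna.tsv", "circRNA"),
      miRNA = read_counts("counts_mirna.tsv", "miRNA")
    ),
    lengths = setNames(lengths_tbl$length, lengths_tbl$transcript_id),
    totals = setNames(totals_tbl$total, totals_tbl$sample),
    gene_models = read_gene_models(p("genome.gff3")),
    predictor_paths = setNames(
      list.files(dir, "^targets_.*\\.tsv$", full.names = TRUE),
      stringr::str_remove(stringr::str_remove(
        list.files(dir, "^targets_.*\\.tsv$"), "^targets_"), "\\.tsv$")
    ),
    caller_paths = setNames(
      list.files(dir, "^junctions_.*\\.bed$", full.names = TRUE),
      stringr::str_remove(stringr::str_remove(
        list.files(dir, "^junctions_.*\\.bed$"), "^junctions_"), "\\.bed$")
    ),
    gene_lists = list(
      TF = readLines(p("tf_genes.txt")),
      leaf_associated = readLines(p("leaf_genes.txt"))
    ),
    lncrna_candidates = cand,
    ground_truth = if (file.exists(gt_path)) read_ground_truth(gt_path)
  )
}
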