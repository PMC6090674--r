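# shared fixtures and independent oracles, built in code at test time

# small, fast generator configuration for unit tests
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(n_mrna = 40, n_lncrna = 6, n_circrna = 8, n_mirna = 20,
             n_planted_pairs = 6, shared_mirnas_per_pair = 4,
             seed = seed, ...)
}

# exhaustive-enumeration oracle for the shared-miRNA hypergeometric tail:
# P(|draw of size K_b| overlaps a fixed K_a-set in >= k elements), all
# C(N, K_b) draws enumerated
hyper_enum_oracle <- function(k, K_a, K_b, N) {
  draws <- utils::combn(N, K_b)
  overlaps <- colSums(draws <= K_a) # fixed K_a-set = {1, ..., K_a}
  mean(overlaps >= k)
}

# brute-force Benjamini-Hochberg: adj_i = min over j >= i(rank) of p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small expression tibble from a named list of numeric vectors
make_expr <- function(rows, samples = NULL, scale = "log2p1",
                      rna_class = NULL) {
  n <- length(rows[[1]])
  samples <- samples %||% paste0("Day", seq(4, by = 2, length.out = n))
  tbl <- tibble::tibble(transcript_id = names(rows))
  if (!is.null(rna_class)) tbl$rna_class <- rna_class
  mat <- do.call(rbind, rows)
  colnames(mat) <- samples
  expression_matrix(dplyr::bind_cols(tbl, tibble::as_tibble(mat)), scale)
}

`%||%` <- rlang::`%||%`

# hand-built gene models on one toy chromosome (0-based half-open):
#   GA: protein-coding, exons [100,200) and [300,400)
#   GB: protein-coding, exons [600,700) and [800,900)
#   GC: non-coding single-exon gene at [1200,1400)
toy_models <- function() {
  tibble::tibble(
    gene_id = c("GA", "GB", "GC"),
    chrom = "Chr1",
    strand = c("+", "+", "-"),
    start = c(100L, 600L, 1200L),
    end = c(400L, 900L, 1400L),
    biotype = c("protein_coding", "protein_coding", "other"),
    exons = list(
      tibble::tibble(start = c(100L, 300L), end = c(200L, 400L)),
      tibble::tibble(start = c(600L, 800L), end = c(700L, 900L)),
      tibble::tibble(start = 1200L, end = 1400L)
    )
  )
}

# long-format junction call rows for merge_junction_calls()
junction_rows <- function(chrom, start, end, strand, reads, samples = "Day4") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = sprintf("%s:%d-%d(%s)", chrom, start, end, strand),
                 reads = reads, strand = strand, sample = samples)
}

# deterministic toy ceRNA network used by the hub / comparison tests
toy_network <- function(pairs, stage = "global") {
  classes <- tibble::tibble(
    target_id = sort(unique(c(pairs$id_a, pairs$id_b))),
    target_class = "mRNA"
  )
  table <- tibble::tibble(
    mirna_id = "miR001",
    target_id = classes$target_id,
    target_class = "mRNA"
  )
  assemble_network(pairs, table, stage_label = stage)
}
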