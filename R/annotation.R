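#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `mRNA` and `exon` features with `ID`/`Parent` links and an
#' optional `biotype` attribute on genes (`protein_coding` assumed for genes
#' with mRNA children when absent). GFF3 coordinates (1-based, closed) are
#' converted to the 0-based half-open convention used internally and in BED
#' output. Exons of all transcripts of a gene are unioned into disjoint
#' intervals.
#'
#' @param path GFF3 file.
#' @return tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `biotype` and a list-column `exons` of tibbles (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  genes <- dplyr::filter(df, .data$type == "gene")
  mrna <- dplyr::filter(df, .data$type == "mRNA")
  exons <- dplyr::filter(df, .data$type == "exon")

  # map exon -> gene through the mRNA parent
  tx2gene <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  exon_gene <- tx2gene[as.character(unlist(exons$Parent))]

  exon_tbl <- tibble(
    gene_id = unname(exon_gene),
    start = exons$start - 1L,
    end = exons$end
  ) |>
    dplyr::filter(!is.na(.data$gene_id))

  exon_list <- exon_tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(~ merge_intervals(.x)) |>
    setNames(dplyr::group_keys(dplyr::group_by(exon_tbl, .data$gene_id))$gene_id)

  biotype <- if ("biotype" %in% names(genes)) {
    as.character(genes$biotype)
  } else {
    ifelse(genes$ID %in% unname(tx2gene), "protein_coding", "other")
  }
  biotype[is.na(biotype)] <- "other"

  tibble(
    gene_id = as.character(genes$ID),
    chrom = genes$seqnames,
    strand = genes$strand,
    start = genes$start - 1L,
    end = genes$end,
    biotype = biotype,
    exons = unname(exon_list[as.character(genes$ID)])
  ) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

# union of possibly overlapping intervals (0-based half-open)
merge_intervals <- function(iv) {
  iv <- arrange(iv, .data$start, .data$end)
  out_start <- out_end <- integer(0)
  for (i in seq_len(nrow(iv))) {
    if (length(out_end) && iv$start[i] <= out_end[length(out_end)]) {
      out_end[length(out_end)] <- max(out_end[length(out_end)], iv$end[i])
    } else {
      out_start <- c(out_start, iv$start[i])
      out_end <- c(out_end, iv$end[i])
    }
  }
  tibble(start = out_start, end = out_end)
}

#' Read back-splice junction calls from a BED6+1 file
#'
#' Headerless tab-separated file with columns chrom, start, end, name, score
#' (junction reads in that sample), strand, sample. Coordinates are 0-based
#' half-open.
#'
#' @param path file of junction calls from one caller.
#' @param caller caller name recorded on every row.
#' @return long tibble: `chrom`, `start`, `end`, `name`, `reads`, `strand`,
#'   `sample`, `caller`.
#' @export
read_junction_calls <- function(path, caller) {
  cols <- c("chrom", "start", "end", "name", "reads", "strand", "sample")
  x <- suppressWarnings(readr::read_tsv(path, col_names = cols,
                                        col_types = "ciicicc",
                                        progress = FALSE))
  bad <- which(is.na(x$start) | is.na(x$end) | is.na(x$reads) | is.na(x$chrom))
  if (length(bad)) {
    abort(paste0("malformed junction record(s) in ", path, " at line(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  mutate(x, caller = caller)
}

#' Merge back-splice junction calls from multiple callers
#'
#' Junctions with identical (chrom, start, end, strand) are unified across
#' callers; per-sample support is the maximum reported by any caller, and the
#' `callers` field accumulates provenance. A junction is retained only when it
#' reaches `min_reads` supporting reads, either in at least one sample
#' (`mode = "per_sample"`, the default) or summed over all samples
#' (`mode = "summed"`).
#'
#' @param call_sets named list of junction tables: either long tables as
#'   returned by [read_junction_calls()] (names supply the caller when no
#'   `caller` column is present), or previously merged wide tables (which
#'   makes the merge idempotent).
#' @param min_reads junction-read support threshold (default 2).
#' @param mode how the threshold is applied across samples.
#' @return wide tibble sorted by coordinate: `junction_id`, `chrom`, `start`,
#'   `end`, `strand`, `callers`, `max_support`, then one support column per
#'   sample.
#' @export
merge_junction_calls <- function(call_sets, min_reads = 2,
                                 mode = c("per_sample", "summed")) {
  mode <- match.arg(mode)
  if (is.data.frame(call_sets)) call_sets <- list(call_sets)
  if (is.null(names(call_sets))) {
    names(call_sets) <- paste0("caller", seq_along(call_sets))
  }
  long <- purrr::imap(call_sets, function(x, nm) {
    if ("junction_id" %in% names(x)) return(unmerge_junctions(x))
    x <- as_tibble(x)
    if (!"caller" %in% names(x)) x$caller <- nm
    x[c("chrom", "start", "end", "strand", "sample", "reads", "caller")]
  }) |> purrr::list_rbind()

  if (nrow(long) == 0) {
    return(tibble(junction_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  callers = character(), max_support = integer()))
  }
  if (any(long$start >= long$end)) abort("junction with start >= end")
  if (any(long$reads < 0)) abort("negative junction-read count")
  check_chrom_consistency(split(long$chrom, long$caller))

  per_sample <- long |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand, .data$sample) |>
    summarise(reads = max(.data$reads), .groups = "drop")
  callers <- long |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(callers = paste(sort(unique(.data$caller)), collapse = ","),
              .groups = "drop")

  wide <- tidyr::pivot_wider(per_sample, names_from = "sample",
                             values_from = "reads", values_fill = 0L)
  sample_names <- sort(setdiff(names(wide), c("chrom", "start", "end", "strand")))
  wide <- wide[c("chrom", "start", "end", "strand", sample_names)]
  support <- as.matrix(wide[sample_names])
  stat <- if (mode == "per_sample") apply(support, 1, max) else rowSums(support)

  dplyr::left_join(wide, callers, by = c("chrom", "start", "end", "strand")) |>
    mutate(
      junction_id = sprintf("%s:%d-%d(%s)", .data$chrom, .data$start,
                            .data$end, .data$strand),
      max_support = as.integer(apply(support, 1, max))
    ) |>
    dplyr::filter(stat >= min_reads) |>
    select("junction_id", "chrom", "start", "end", "strand",
           "callers", "max_support", dplyr::all_of(sample_names)) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

# wide merged table -> long per-caller records (callers provenance preserved)
unmerge_junctions <- function(x) {
  samples <- setdiff(names(x), c("junction_id", "chrom", "start", "end",
                                 "strand", "callers", "max_support",
                                 "circ_class", "parent_genes"))
  x |>
    tidyr::separate_rows("callers", sep = ",") |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample",
                        values_to = "reads") |>
    dplyr::rename(caller = "callers") |>
    select("chrom", "start", "end", "strand", "sample", "reads", "caller")
}

check_chrom_consistency <- function(chroms_by_file) {
  style <- function(v) {
    pre <- stringr::str_match(unique(v), "^([A-Za-z]+)")[, 2]
    pre[is.na(pre)] <- "<numeric>"
    sort(unique(pre))
  }
  styles <- purrr::map(chroms_by_file, style)
  if (length(unique(purrr::map_chr(styles, paste, collapse = "/"))) > 1) {
    offenders <- purrr::imap_chr(chroms_by_file, function(v, nm) {
      paste0(nm, ": ", paste(sort(unique(v)), collapse = ","))
    })
    abort(paste0("inconsistent chromosome naming across junction files:\n",
                 paste(offenders, collapse = "\n")))
  }
  invisible(TRUE)
}

#' Classify circRNA junctions by genomic context
#'
#' Every junction receives exactly one class:
#' * `exonic` - both back-splice endpoints fall within exons of exactly one
#'   protein-coding gene;
#' * `intronic` - the full span lies within a single intron of one gene;
#' * `intergenic` - the span overlaps no gene;
#' * `other` - anything else, notably spans touching two or more
#'   protein-coding genes.
#'
#' Junctions with unknown strand (`.`) are classified against genes on both
#' strands. `parent_genes` lists the overlapped gene(s) (comma-joined) for
#' non-intergenic classes; for `exonic` it is the single protein-coding gene.
#'
#' @param junctions merged junction tibble (see [merge_junction_calls()]).
#' @param models gene-model tibble from [read_gene_models()].
#' @return `junctions` with `circ_class` and `parent_genes` columns added.
#' @export
classify_circ_junctions <- function(junctions, models) {
  if (nrow(junctions) == 0) {
    return(mutate(junctions, circ_class = character(0), parent_genes = character(0)))
  }
  res <- purrr::pmap(
    junctions[c("chrom", "start", "end", "strand")],
    function(chrom, start, end, strand) {
      hits <- models[models$chrom == chrom &
                       models$start < end & start < models$end &
                       (strand == "." | models$strand == strand), , drop = FALSE]
      if (nrow(hits) == 0) {
        return(list(class = "intergenic", parents = ""))
      }
      coding <- hits[hits$biotype == "protein_coding", , drop = FALSE]
      if (nrow(coding) == 1) {
        ex <- coding$exons[[1]]
        in_exon <- function(pos) any(ex$start <= pos & pos < ex$end)
        if (in_exon(start) && in_exon(end - 1L)) {
          return(list(class = "exonic", parents = coding$gene_id))
        }
      }
      if (nrow(hits) == 1) {
        ex <- hits$exons[[1]]
        if (nrow(ex) > 1) {
          introns <- tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
          if (any(introns$start <= start & end <= introns$end)) {
            return(list(class = "intronic", parents = hits$gene_id))
          }
        }
      }
      list(class = "other",
           parents = paste(sort(hits$gene_id), collapse = ","))
    }
  )
  mutate(junctions,
         circ_class = purrr::map_chr(res, "class"),
         parent_genes = purrr::map_chr(res, "parents"))
}

#' Length of the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames of each (stranded) transcript sequence for
#' ATG-initiated, stop-terminated reading frames and returns the longest one
#' in amino acids (the stop codon is not counted); 0 when none exists. Codons
#' containing N are treated as unknown residues: neither starts nor stops.
#'
#' @param sequences character vector of nucleotide sequences over
#'   \{A, C, G, T, N\} (case-insensitive).
#' @return integer vector of amino-acid lengths.
#' @export
longest_orf <- function(sequences) {
  vapply(sequences, function(s) {
    s <- toupper(s)
    if (stringr::str_detect(s, "[^ACGTN]")) {
      abort("sequence contains non-nucleotide characters")
    }
    best <- 0L
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3
      if (n_codon < 2) next
      codons <- substring(s, frame + 1 + 3 * (seq_len(n_codon) - 1),
                          frame + 3 * seq_len(n_codon))
      starts <- which(codons == "ATG")
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (!length(starts) || !length(stops)) next
      for (st in starts) {
        after <- stops[stops > st]
        if (length(after)) {
          best <- max(best, after[1] - st)
          # later starts in this frame can only give shorter ORFs up to the
          # same stop; still scan them, a start past the stop opens a new ORF
        }
      }
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter novel lncRNA candidates
#'
#' Retains assembled transcripts with class code `i`, `x` or `u`, length of at
#' least `min_len` nucleotides and a longest ORF no longer than `max_orf`
#' amino acids (both boundaries inclusive). When a logical `coding` column is
#' present (precomputed coding-potential call), candidates flagged coding are
#' rejected first.
#'
#' @param candidates tibble with columns `transcript_id`, `class_code` and
#'   either `sequence` or precomputed `length` / `longest_orf_aa` columns.
#' @param min_len minimum transcript length in nt (default 200).
#' @param max_orf maximum ORF length in amino acids (default 120).
#' @return the retained rows, with `length` and `longest_orf_aa` filled in.
#' @export
filter_lncrna_candidates <- function(candidates, min_len = 200, max_orf = 120) {
  x <- as_tibble(candidates)
  if (!"length" %in% names(x)) x$length <- nchar(x$sequence)
  if (!"longest_orf_aa" %in% names(x)) x$longest_orf_aa <- longest_orf(x$sequence)
  keep <- x$class_code %in% c("i", "x", "u") &
    x$length >= min_len &
    x$longest_orf_aa <= max_orf
  if ("coding" %in% names(x)) keep <- keep & !x$coding
  x[keep, , drop = FALSE]
}
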