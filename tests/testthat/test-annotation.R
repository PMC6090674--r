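test_that("junction merge unifies callers, takes max support, filters low reads", {
  a <- junction_rows("Chr1", 100L, 500L, "+", 3L)
  b <- junction_rows("Chr1", 100L, 500L, "+", 1L)
  merged <- merge_junction_calls(list(A = a, B = b))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$callers, "A,B")
  expect_equal(merged$Day4, 3L)
  expect_equal(merged$max_support, 3L)

  # a junction with a single read in every sample is removed
  single <- dplyr::bind_rows(
    junction_rows("Chr1", 100L, 500L, "+", 2L, c("Day4")),
    junction_rows("Chr1", 900L, 1300L, "+", 1L, c("Day4"))
  )
  single2 <- dplyr::bind_rows(single,
                              junction_rows("Chr1", 900L, 1300L, "+", 1L, "Day6"))
  out <- merge_junction_calls(list(A = single2))
  expect_equal(out$junction_id, "Chr1:100-500(+)")

  # summed mode counts reads across samples
  out_sum <- merge_junction_calls(list(A = single2), mode = "summed")
  expect_equal(nrow(out_sum), 2)

  # empty inputs give an empty table, not an error
  empty <- merge_junction_calls(list(A = a[0, ]))
  expect_equal(nrow(empty), 0)

  # merging the merged output with itself changes nothing
  again <- merge_junction_calls(list(merged))
  expect_equal(again, merged)

  # order of input rows does not matter
  shuffled <- merge_junction_calls(list(A = a[nrow(a):1, ], B = b))
  expect_equal(shuffled, merged)
})

test_that("inconsistent chromosome naming across callers is a hard error", {
  a <- junction_rows("Chr1", 100L, 500L, "+", 3L)
  b <- junction_rows("chr1", 100L, 500L, "+", 2L)
  expect_error(merge_junction_calls(list(A = a, B = b)), "inconsistent")
})

test_that("junction reader validates records with line numbers", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t10\t200\tj1\t3\t+\tDay4",
               "Chr1\tXX\t300\tj2\t2\t+\tDay4"), path)
  expect_error(read_junction_calls(path, "A"), "line")
  writeLines("Chr1\t10\t200\tj1\t3\t+\tDay4", path)
  ok <- read_junction_calls(path, "A")
  expect_equal(ok$caller, "A")
  expect_equal(ok$reads, 3L)
})

test_that("circRNA classification follows the genomic-context rules", {
  models <- toy_models()
  junctions <- tibble::tibble(
    chrom = "Chr1",
    start = c(150L, 120L, 210L, 2000L, 1250L),
    end = c(350L, 850L, 290L, 2100L, 1350L),
    strand = c("+", ".", "+", ".", "-")
  )
  out <- classify_circ_junctions(junctions, models)
  # both endpoints in exons of GA only -> exonic
  expect_equal(out$circ_class[1], "exonic")
  expect_equal(out$parent_genes[1], "GA")
  # spans GA and GB -> other
  expect_equal(out$circ_class[2], "other")
  expect_equal(out$parent_genes[2], "GA,GB")
  # fully inside GA's intron -> intronic
  expect_equal(out$circ_class[3], "intronic")
  # gene desert -> intergenic
  expect_equal(out$circ_class[4], "intergenic")
  expect_equal(out$parent_genes[4], "")
  # inside the single exon of a NON-coding gene: not exonic by definition
  expect_equal(out$circ_class[5], "other")

  # strand-aware: a '+' junction inside GC's span ignores the '-' gene
  minus_side <- classify_circ_junctions(
    tibble::tibble(chrom = "Chr1", start = 1250L, end = 1350L, strand = "+"),
    models)
  expect_equal(minus_side$circ_class, "intergenic")

  # classification is a partition: every junction gets exactly one class
  expect_true(all(out$circ_class %in%
                    c("exonic", "intronic", "intergenic", "other")))
})

test_that("classification matches ground truth and a GenomicRanges oracle", {
  ds <- simulate_dataset(tiny_sim_config(seed = 4))
  models <- ds$genome$genes[c("gene_id", "chrom", "strand", "start", "end",
                              "biotype", "exons")]
  junc <- ds$junctions
  out <- classify_circ_junctions(junc, models)
  expect_equal(out$circ_class, junc$true_class)
  non_intergenic <- junc$true_class != "intergenic"
  expect_equal(out$parent_genes[non_intergenic],
               junc$true_parents[non_intergenic])

  # independent overlap scan through GenomicRanges
  gene_gr <- GenomicRanges::GRanges(models$chrom,
                                    IRanges::IRanges(models$start + 1, models$end),
                                    strand = models$strand)
  junc_gr <- GenomicRanges::GRanges(junc$chrom,
                                    IRanges::IRanges(junc$start + 1, junc$end),
                                    strand = "*")
  hits <- GenomicRanges::findOverlaps(junc_gr, gene_gr, ignore.strand = TRUE)
  for (i in seq_len(nrow(junc))) {
    g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    g <- g[junc$strand[i] == "." | models$strand[g] == junc$strand[i]]
    oracle_class <- if (length(g) == 0) {
      "intergenic"
    } else if (length(g) == 1 &&
               models$biotype[g] == "protein_coding" && {
                 ex <- models$exons[[g]]
                 any(ex$start <= junc$start[i] & junc$start[i] < ex$end) &&
                   any(ex$start <= junc$end[i] - 1 & junc$end[i] - 1 < ex$end)
               }) {
      "exonic"
    } else if (length(g) == 1 && {
      ex <- models$exons[[g]]
      nrow(ex) > 1 &&
        any(ex$end[-nrow(ex)] <= junc$start[i] & junc$end[i] <= ex$start[-1])
    }) {
      "intronic"
    } else {
      "other"
    }
    expect_equal(out$circ_class[i], oracle_class)
  }
})

test_that("longest ORF scans three forward frames for ATG..stop", {
  expect_equal(longest_orf("ATGAAATAG"), 2L) # Met-Lys
  expect_equal(longest_orf("CCCCCC"), 0L)    # no ATG
  expect_equal(longest_orf("ATGAAA"), 0L)    # no stop: not an ORF
  # frame-shifted ORF (one leading base)
  expect_equal(longest_orf("CATGAAATAG"), 2L)
  # 363 nt encoding exactly a 120-aa ORF (boundary of the lncRNA filter)
  set.seed(9)
  body <- paste(replicate(119, paste(sample(c("C", "G", "T"), 3, TRUE),
                                     collapse = "")), collapse = "")
  seq363 <- paste0("ATG", body, "TAA")
  expect_equal(nchar(seq363), 363L)
  expect_equal(longest_orf(seq363), 120L)
  expect_error(longest_orf("ATGXXX"), "non-nucleotide")

  # oracle: exhaustive scan over every (start, frame) via substrings
  orf_oracle <- function(s) {
    best <- 0L
    for (i in seq_len(max(nchar(s) - 5, 0))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= nchar(s)) {
        cod <- substr(s, j, j + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (j - i) %/% 3)
          break
        }
        j <- j + 3
      }
    }
    best
  }
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1), TRUE),
               collapse = "")
    expect_equal(longest_orf(s), orf_oracle(s))
  }
})

test_that("lncRNA candidate filter applies class, length and ORF rules", {
  cand <- tibble::tibble(
    transcript_id = paste0("c", 1:6),
    class_code = c("u", "u", "u", "j", "i", "x"),
    length = c(199L, 200L, 400L, 400L, 250L, 300L),
    longest_orf_aa = c(10L, 120L, 121L, 10L, 0L, 120L)
  )
  kept <- filter_lncrna_candidates(cand)
  expect_equal(kept$transcript_id, c("c2", "c5", "c6")) # inclusive boundaries
  # precomputed coding-potential flag rejects before the length/ORF rules
  cand$coding <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(filter_lncrna_candidates(cand)$transcript_id, c("c5", "c6"))

  # computed from sequence when lengths/ORFs are absent
  ds_cand <- simulate_dataset(tiny_sim_config())$lncrna_candidates
  kept2 <- filter_lncrna_candidates(
    ds_cand[c("transcript_id", "class_code", "sequence")])
  expect_equal(kept2$transcript_id,
               ds_cand$transcript_id[ds_cand$truth_retained])
})

test_that("gene models survive a GFF3 round trip", {
  ds <- simulate_dataset(tiny_sim_config())
  dir <- withr::local_tempdir()
  cernaforge:::write_gene_models_gff3(ds$genome$genes, ds$genome$chrom_lengths,
                                      file.path(dir, "g.gff3"))
  models <- read_gene_models(file.path(dir, "g.gff3"))
  orig <- dplyr::arrange(ds$genome$genes, chrom, start, gene_id)
  expect_equal(models$gene_id, orig$gene_id)
  expect_equal(models$start, orig$start)
  expect_equal(models$end, orig$end)
  expect_equal(models$strand, orig$strand)
  expect_equal(models$biotype, orig$biotype)
  for (i in seq_len(nrow(models))) {
    expect_equal(as.data.frame(models$exons[[i]]),
                 as.data.frame(orig$exons[[i]]))
  }
})
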