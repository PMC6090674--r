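#' Configuration for the synthetic leaf time-series generator
#'
#' The defaults emulate the study design the package targets: 14 time points
#' sampled every 2 days from Day 4 to Day 30, four RNA classes, two replicate
#' series, 30 planted ceRNA pairs each sharing 5 miRNA regulators from a
#' 50-miRNA universe, and six archetypal temporal shapes.
#'
#' @param n_timepoints number of time points (days 4, 6, ... at 2-day steps).
#' @param n_mrna,n_lncrna,n_circrna,n_mirna transcript counts per class.
#' @param n_planted_pairs number of planted ceRNA pairs.
#' @param shared_mirnas_per_pair miRNAs shared by each planted pair.
#' @param background_targets_per_rna background miRNA regulators drawn
#'   independently for every RNA (planted members included).
#' @param profile_noise_sd replicate-level Gaussian noise, log2 units.
#' @param pair_profile_sd per-pair latent deviation shared by both members of
#'   a planted pair (keeps even the flat archetype reproducible), log2 units.
#' @param background_profile_sd temporal variation of background transcripts
#'   (independent across transcripts and time points), log2 units.
#' @param mirna_stage_shift_sd per-miRNA mean shift between the growth
#'   (Day 4-18) and senescence (Day 20-30) phases, log2 units. Strong stage
#'   regulation of miRNAs is the realistic regime in leaf development (the
#'   miR156/miR172 aging pathway); this plants the two-stage structure the
#'   sample clustering and the stage t-test are meant to detect.
#' @param rna_stage_shift_sd milder stage mean shift for background mRNA,
#'   lncRNA and circRNA transcripts, log2 units (planted members carry their
#'   stage dynamics in the archetype shapes).
#' @param archetype_amplitude archetype amplitude in log2 units.
#' @param nb_dispersion negative-binomial dispersion of the counts.
#' @param n_replicates replicate series per time point.
#' @param library_size mapped reads per sample (jittered +-10% per sample).
#' @param cluster_archetypes number of archetypal temporal shapes (max 6).
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 14,
                       n_mrna = 200, n_lncrna = 20, n_circrna = 30,
                       n_mirna = 50,
                       n_planted_pairs = 30,
                       shared_mirnas_per_pair = 5,
                       background_targets_per_rna = 2,
                       profile_noise_sd = 0.3,
                       pair_profile_sd = 0.8,
                       background_profile_sd = 0.8,
                       mirna_stage_shift_sd = 2.5,
                       rna_stage_shift_sd = 0.5,
                       archetype_amplitude = 1.5,
                       nb_dispersion = 0.1,
                       n_replicates = 2,
                       library_size = 1e7,
                       cluster_archetypes = 6,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- cfg[c("n_timepoints", "n_mrna", "n_lncrna", "n_circrna", "n_mirna",
                  "n_planted_pairs", "shared_mirnas_per_pair",
                  "background_targets_per_rna", "n_replicates",
                  "cluster_archetypes")]
  if (any(unlist(counts) < 1)) {
    abort("all counts must be >= 1", class = "cernaforge_config_error")
  }
  if (cfg$profile_noise_sd < 0 || cfg$nb_dispersion < 0) {
    abort("noise and dispersion must be >= 0", class = "cernaforge_config_error")
  }
  if (cfg$cluster_archetypes > 6) {
    abort("at most 6 archetypal shapes are defined",
          class = "cernaforge_config_error")
  }
  # a planted member needs shared + 2 * background distinct miRNAs (background
  # targets of the two members are kept disjoint from the shared set and from
  # each other so that the pair shares *exactly* shared_mirnas_per_pair)
  if (cfg$shared_mirnas_per_pair + 2 * cfg$background_targets_per_rna > cfg$n_mirna) {
    abort("target-set sizes infeasible for the miRNA universe",
          class = "cernaforge_config_error")
  }
  n_rna <- cfg$n_mrna + cfg$n_lncrna + cfg$n_circrna
  if (2 * cfg$n_planted_pairs > n_rna) {
    abort("not enough transcripts for the planted pairs",
          class = "cernaforge_config_error")
  }
  structure(cfg, class = c("sim_config", "list"))
}

# six archetypal temporal shapes, z-scored over the time grid (flat stays 0)
archetype_profiles <- function(n_timepoints, amplitude) {
  # parameterized so that no two shapes are strongly positively correlated
  # (max pairwise r ~ 0.35): six distinct clusters presuppose distinguishable
  # shapes, and positive cross-shape correlation would also leak through the
  # co-expression filter
  t <- seq(0, 1, length.out = n_timepoints)
  shapes <- rbind(
    early_high_decaying = exp(-t / 0.2),
    rise_then_fall = exp(-((t - 0.28) / 0.13)^2),
    flat = rep(0, n_timepoints),
    late_rising = stats::plogis((t - 0.85) / 0.05),
    mid_peak = exp(-((t - 0.52) / 0.11)^2),
    monotone_increasing = 1 - exp(-t / 0.15)
  )
  t(apply(shapes, 1, function(z) {
    if (stats::sd(z) == 0) return(z)
    amplitude * (z - mean(z)) / stats::sd(z)
  }))
}

#' Generate a synthetic leaf-development dataset with planted ground truth
#'
#' Produces every input the pipeline consumes: raw count tables for the four
#' RNA classes over replicate time series, miRNA-target predictions from two
#' partially overlapping predictors, back-splice junction calls from two
#' callers (including one decoy junction supported by a single read), toy
#' GFF3 gene models and transcript sequences, annotation gene lists, plus the
#' planted ground truth.
#'
#' Planted pair members share exactly `shared_mirnas_per_pair` miRNAs and
#' follow a shared latent profile (archetype plus a pair-level deviation);
#' background transcripts have independently drawn target sets and
#' independent temporal profiles. Counts are negative-binomial around the
#' latent means. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list with the simulated tables, the toy genome, the latent
#'   `profiles` matrix (log2 scale, replicate-free) and `ground_truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  days <- seq(4, by = 2, length.out = cfg$n_timepoints)
  timepoints <- paste0("Day", days)
  samples <- as.vector(t(outer(timepoints, seq_len(cfg$n_replicates),
                               function(tp, r) paste0(tp, "_R", r))))
  if (cfg$n_replicates == 1) samples <- timepoints

  ## ---- toy genome and gene models ------------------------------------------
  genome <- build_toy_genome(cfg$n_mrna)
  genes <- genome$genes
  mrna_ids <- genes$gene_id
  lnc_ids <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  mir_ids <- sprintf("miR%03d", seq_len(cfg$n_mirna))

  ## ---- circRNA junction placement ------------------------------------------
  junc <- place_junctions(genes, cfg$n_circrna)
  circ_ids <- junc$junction_id[!junc$decoy]

  rna_ids <- c(mrna_ids, lnc_ids, circ_ids)
  rna_class <- c(rep("mRNA", cfg$n_mrna), rep("lncRNA", cfg$n_lncrna),
                 rep("circRNA", cfg$n_circrna))
  names(rna_class) <- rna_ids

  ## ---- planted pairs and target sets ---------------------------------------
  members <- sample(rna_ids, 2 * cfg$n_planted_pairs)
  pair_a <- members[seq_len(cfg$n_planted_pairs)]
  pair_b <- members[cfg$n_planted_pairs + seq_len(cfg$n_planted_pairs)]
  planted_pairs <- tibble(
    id_a = pmin(pair_a, pair_b),
    id_b = pmax(pair_a, pair_b),
    archetype = rep(seq_len(cfg$cluster_archetypes),
                    length.out = cfg$n_planted_pairs)
  )

  target_edges <- vector("list", length(rna_ids))
  names(target_edges) <- rna_ids
  for (i in seq_len(cfg$n_planted_pairs)) {
    shared <- sample(mir_ids, cfg$shared_mirnas_per_pair)
    rest <- setdiff(mir_ids, shared)
    bg <- sample(rest, 2 * cfg$background_targets_per_rna)
    a <- pair_a[i]; b <- pair_b[i]
    target_edges[[a]] <- c(shared, bg[seq_len(cfg$background_targets_per_rna)])
    target_edges[[b]] <- c(shared, bg[cfg$background_targets_per_rna +
                                        seq_len(cfg$background_targets_per_rna)])
  }
  background_ids <- setdiff(rna_ids, members)
  for (id in background_ids) {
    target_edges[[id]] <- sample(mir_ids, cfg$background_targets_per_rna)
  }
  targets <- tibble(
    mirna_id = unlist(target_edges, use.names = FALSE),
    target_id = rep(rna_ids, lengths(target_edges))
  ) |>
    mutate(target_class = rna_class[.data$target_id]) |>
    arrange(.data$mirna_id, .data$target_id)

  ## ---- latent temporal profiles (log2 scale) -------------------------------
  arch <- archetype_profiles(cfg$n_timepoints, cfg$archetype_amplitude)
  n_rna_all <- length(rna_ids)
  baseline <- ifelse(rna_class == "circRNA",
                     stats::runif(n_rna_all, 2.5, 4.5),
                     stats::runif(n_rna_all, 2.5, 6.5))
  names(baseline) <- rna_ids
  profiles <- matrix(0, n_rna_all, cfg$n_timepoints,
                     dimnames = list(rna_ids, timepoints))
  senescent <- days >= 20
  for (id in background_ids) {
    profiles[id, ] <- baseline[id] +
      stats::rnorm(cfg$n_timepoints, 0, cfg$background_profile_sd) +
      stats::rnorm(1, 0, cfg$rna_stage_shift_sd) * senescent
  }
  for (i in seq_len(cfg$n_planted_pairs)) {
    shape <- arch[planted_pairs$archetype[i], ] +
      stats::rnorm(cfg$n_timepoints, 0, cfg$pair_profile_sd)
    profiles[pair_a[i], ] <- baseline[pair_a[i]] + shape
    profiles[pair_b[i], ] <- baseline[pair_b[i]] + shape
  }
  mir_profiles <- matrix(
    stats::runif(cfg$n_mirna, 2, 5) +
      stats::rnorm(cfg$n_mirna * cfg$n_timepoints, 0, cfg$background_profile_sd),
    cfg$n_mirna, cfg$n_timepoints, dimnames = list(mir_ids, timepoints)
  ) + stats::rnorm(cfg$n_mirna, 0, cfg$mirna_stage_shift_sd) %o% as.numeric(senescent)

  ## ---- counts ---------------------------------------------------------------
  totals <- round(cfg$library_size *
                    stats::runif(length(samples), 0.9, 1.1))
  names(totals) <- samples
  lengths <- c(
    setNames(genes$tx_length, mrna_ids),
    setNames(round(stats::runif(cfg$n_lncrna, 300, 1500)), lnc_ids)
  )

  log2_noisy <- function(latent) {
    # one noisy realization per sample; latent indexed by time point
    tp_of <- sample_timepoint(samples)
    vapply(seq_along(samples), function(j) {
      latent[, tp_of[j]] +
        stats::rnorm(nrow(latent), 0, cfg$profile_noise_sd)
    }, numeric(nrow(latent)))
  }
  nb_counts <- function(mu) {
    m <- matrix(
      stats::rnbinom(length(mu), mu = pmax(as.vector(mu), 1e-8),
                     size = 1 / max(cfg$nb_dispersion, 1e-8)),
      nrow(mu), ncol(mu), dimnames = dimnames(mu)
    )
    m
  }

  lin_ml <- log2_noisy(profiles[c(mrna_ids, lnc_ids), , drop = FALSE])
  dimnames(lin_ml) <- list(c(mrna_ids, lnc_ids), samples)
  mu_ml <- (2^lin_ml - 1) *
    (lengths[c(mrna_ids, lnc_ids)] / 1e3) %o% (totals / 1e6)
  counts_ml <- nb_counts(mu_ml)

  lin_mir <- log2_noisy(mir_profiles)
  dimnames(lin_mir) <- list(mir_ids, samples)
  mu_mir <- (2^lin_mir - 1) * rep(1, cfg$n_mirna) %o% (totals / 1e6)
  counts_mir <- nb_counts(mu_mir)

  lin_circ <- log2_noisy(profiles[circ_ids, , drop = FALSE])
  dimnames(lin_circ) <- list(circ_ids, samples)
  counts_circ <- nb_counts(2^lin_circ - 1)

  as_count_tbl <- function(m, cls) {
    dplyr::bind_cols(
      tibble(transcript_id = rownames(m), rna_class = cls),
      as_tibble(m)
    ) |> expression_matrix("raw_count")
  }
  counts <- list(
    mRNA = as_count_tbl(counts_ml[mrna_ids, , drop = FALSE], "mRNA"),
    lncRNA = as_count_tbl(counts_ml[lnc_ids, , drop = FALSE], "lncRNA"),
    circRNA = as_count_tbl(counts_circ, "circRNA"),
    miRNA = as_count_tbl(counts_mir, "miRNA")
  )

  ## ---- junction caller tables ----------------------------------------------
  callers <- make_caller_tables(junc, counts_circ, samples)

  ## ---- predictor tables -----------------------------------------------------
  n_edges <- nrow(targets)
  in_a <- stats::runif(n_edges) < 0.8
  in_b <- !in_a | stats::runif(n_edges) < 0.6
  pred_a <- mutate(targets[in_a, ], predictors = "predictorA")
  pred_b <- mutate(targets[in_b, ], predictors = "predictorB")

  ## ---- annotation gene lists (enriched in planted members) -----------------
  planted_mrna <- intersect(members, mrna_ids)
  tf_genes <- unique(c(
    utils::head(planted_mrna, 20),
    sample(setdiff(mrna_ids, planted_mrna), 15)
  ))
  leaf_genes <- unique(c(
    utils::head(planted_mrna, 30),
    sample(setdiff(mrna_ids, planted_mrna), 25)
  ))

  ## ---- lncRNA candidate transcripts ----------------------------------------
  candidates <- make_lncrna_candidates()

  ground_truth <- list(
    planted_pairs = planted_pairs,
    cluster_assignment = tibble(
      transcript_id = c(pair_a, pair_b),
      archetype = rep(planted_pairs$archetype, 2)
    ) |> arrange(.data$transcript_id),
    stage_labels = tibble(
      timepoint = timepoints,
      stage = ifelse(days <= 18, "growth", "senescence")
    ),
    circ_classes = select(junc, "junction_id", circ_class = "true_class"),
    low_support_junction = junc$junction_id[junc$decoy],
    annotated_gene_sets = list(TF = sort(tf_genes),
                               leaf_associated = sort(leaf_genes)),
    lncrna_candidates_retained = candidates$transcript_id[candidates$truth_retained]
  )

  list(
    config = cfg,
    days = days, timepoints = timepoints, samples = samples,
    genome = genome,
    junctions = junc,
    counts = counts,
    lengths = lengths,
    totals = totals,
    targets = targets,
    predictor_tables = list(predictorA = pred_a, predictorB = pred_b),
    caller_tables = callers,
    gene_lists = list(TF = sort(tf_genes), leaf_associated = sort(leaf_genes)),
    lncrna_candidates = candidates,
    profiles = profiles,
    mir_profiles = mir_profiles,
    ground_truth = ground_truth
  )
}

# lay out n genes with 2-5 exons on two chromosomes
build_toy_genome <- function(n_genes) {
  chrom_of <- rep(c("Chr1", "Chr2"), length.out = n_genes)
  gene_rows <- vector("list", n_genes)
  exon_rows <- vector("list", n_genes)
  cursor <- c(Chr1 = 1000L, Chr2 = 1000L)
  for (i in seq_len(n_genes)) {
    chrom <- chrom_of[i]
    n_exons <- sample(2:5, 1)
    exon_len <- sample(100:200, n_exons, replace = TRUE)
    intron_len <- if (n_exons > 1) sample(80:150, n_exons - 1, replace = TRUE) else integer(0)
    start <- cursor[[chrom]]
    ex_start <- start + c(0L, cumsum(exon_len[-n_exons] + intron_len))
    ex_end <- ex_start + exon_len
    gene_id <- sprintf("G%04d", i)
    strand <- sample(c("+", "-"), 1)
    gene_rows[[i]] <- tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = start, end = ex_end[n_exons],
      biotype = "protein_coding", n_exons = n_exons,
      tx_length = sum(exon_len)
    )
    exon_rows[[i]] <- tibble(gene_id = gene_id, start = ex_start, end = ex_end)
    cursor[[chrom]] <- ex_end[n_exons] + sample(250:450, 1)
  }
  genes <- purrr::list_rbind(gene_rows)
  exons <- purrr::list_rbind(exon_rows)
  exon_list <- split(exons[c("start", "end")], exons$gene_id)
  genes$exons <- unname(exon_list[genes$gene_id])
  genes$exons <- purrr::map(genes$exons, as_tibble)
  list(
    genes = genes,
    chrom_lengths = c(Chr1 = unname(cursor["Chr1"]) + 5000L,
                      Chr2 = unname(cursor["Chr2"]) + 5000L)
  )
}

# place exonic / intronic / intergenic / "other" junctions on the toy genome,
# plus one exonic decoy junction that will carry a single supporting read
place_junctions <- function(genes, n_circ) {
  n_exonic <- max(1L, n_circ - 6L)
  n_rest <- n_circ - n_exonic # >= 0, split over the three minor classes
  class_plan <- c(rep("exonic", n_exonic),
                  rep(c("intronic", "intergenic", "other"),
                      length.out = n_rest))
  multi <- genes[genes$n_exons >= 2, ]
  used_genes <- character(0)
  rows <- vector("list", length(class_plan) + 1L)
  n_intergenic <- 0L
  n_other <- 0L
  for (i in seq_along(class_plan)) {
    cls <- class_plan[i]
    if (cls == "exonic") {
      g <- multi[!multi$gene_id %in% used_genes, ][1, ]
      used_genes <- c(used_genes, g$gene_id)
      ex <- g$exons[[1]]
      rows[[i]] <- tibble(chrom = g$chrom, start = ex$start[1] + 10L,
                          end = ex$end[min(2, nrow(ex))] - 10L,
                          strand = g$strand, true_class = "exonic",
                          true_parents = g$gene_id)
    } else if (cls == "intronic") {
      g <- multi[!multi$gene_id %in% used_genes, ][1, ]
      used_genes <- c(used_genes, g$gene_id)
      ex <- g$exons[[1]]
      rows[[i]] <- tibble(chrom = g$chrom, start = ex$end[1] + 5L,
                          end = ex$start[2] - 5L, strand = g$strand,
                          true_class = "intronic", true_parents = g$gene_id)
    } else if (cls == "intergenic") {
      # distinct intergenic gaps on Chr2, counted from the chromosome end
      g2 <- genes[genes$chrom == "Chr2", ]
      n_intergenic <- n_intergenic + 1L
      g <- g2[nrow(g2) - n_intergenic + 1L, ]
      rows[[i]] <- tibble(chrom = "Chr2", start = g$end + 30L,
                          end = g$end + 130L, strand = ".",
                          true_class = "intergenic", true_parents = "")
    } else {
      # span two consecutive genes on Chr1, distinct pairs per junction
      g1 <- genes[genes$chrom == "Chr1", ]
      n_other <- n_other + 1L
      j <- nrow(g1) - 2L * n_other
      ga <- g1[j, ]; gb <- g1[j + 1L, ]
      rows[[i]] <- tibble(chrom = "Chr1", start = ga$start + 20L,
                          end = gb$start + 40L, strand = ".",
                          true_class = "other",
                          true_parents = paste(sort(c(ga$gene_id, gb$gene_id)),
                                               collapse = ","))
    }
  }
  # decoy: a well-formed exonic junction supported by a single read everywhere
  g <- multi[!multi$gene_id %in% used_genes, ][1, ]
  ex <- g$exons[[1]]
  rows[[length(class_plan) + 1L]] <- tibble(
    chrom = g$chrom, start = ex$start[1] + 20L,
    end = ex$end[min(2, nrow(ex))] - 20L, strand = g$strand,
    true_class = "exonic", true_parents = g$gene_id
  )
  junc <- purrr::list_rbind(rows) |>
    mutate(
      junction_id = sprintf("%s:%d-%d(%s)", .data$chrom, .data$start,
                            .data$end, .data$strand),
      decoy = dplyr::row_number() > length(class_plan)
    )
  stopifnot(!anyDuplicated(junc$junction_id))
  junc
}

# two caller tables whose per-sample maxima equal the true junction counts
make_caller_tables <- function(junc, counts_circ, samples) {
  real <- junc[!junc$decoy, ]
  n <- nrow(real)
  in_a <- rep(TRUE, n); in_a[seq(3, n, by = 7)] <- FALSE
  in_b <- rep(TRUE, n); in_b[seq(5, n, by = 9)] <- FALSE
  in_b <- in_b | !in_a # union must cover every junction
  long <- function(keep, full_reads) {
    idx <- which(keep)
    purrr::map(idx, function(i) {
      reads <- counts_circ[real$junction_id[i], ]
      if (!full_reads) {
        reads <- floor(reads * stats::runif(length(reads), 0.6, 1))
      }
      tibble(chrom = real$chrom[i], start = real$start[i], end = real$end[i],
             name = real$junction_id[i], reads = as.integer(reads),
             strand = real$strand[i], sample = samples)
    }) |> purrr::list_rbind()
  }
  caller_a <- long(in_a, full_reads = TRUE)
  # caller B reports the true count where A misses the junction, less otherwise
  b_full <- long(in_b & !in_a, full_reads = TRUE)
  b_part <- long(in_b & in_a, full_reads = FALSE)
  decoy <- junc[junc$decoy, ]
  decoy_rows <- tibble(
    chrom = decoy$chrom, start = decoy$start, end = decoy$end,
    name = decoy$junction_id, reads = 1L, strand = decoy$strand,
    sample = list(samples)
  ) |> tidyr::unnest("sample")
  list(
    callerA = arrange(dplyr::bind_rows(caller_a, decoy_rows),
                      .data$chrom, .data$start, .data$sample),
    callerB = arrange(dplyr::bind_rows(b_full, b_part),
                      .data$chrom, .data$start, .data$sample)
  )
}

# small panel of assembled-transcript candidates with designed ORF content
make_lncrna_candidates <- function() {
  filler <- function(n) {
    # alphabet without A: cannot contain ATG or any stop codon
    paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  orf <- function(n_aa) {
    body <- vapply(seq_len(n_aa - 1), function(i) {
      paste(sample(c("C", "G", "T"), 3, replace = TRUE), collapse = "")
    }, character(1))
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  mk <- function(len, orf_aa) {
    core <- if (orf_aa > 0) orf(orf_aa) else ""
    pad <- len - nchar(core)
    left <- pad %/% 2 - (pad %/% 2) %% 3 # keep the designed ORF in frame 1
    paste0(filler(left), core, filler(pad - left))
  }
  spec <- tibble(
    transcript_id = sprintf("CAND%02d", 1:12),
    class_code = c("u", "u", "i", "x", "u", "j", "u", "i", "x", "u", "u", "="),
    len = c(250, 199, 600, 400, 363, 500, 200, 1000, 366, 320, 150, 400),
    orf_aa = c(10, 5, 40, 0, 120, 10, 0, 121, 120, 60, 4, 20)
  )
  spec |>
    mutate(
      sequence = purrr::map2_chr(.data$len, .data$orf_aa, mk),
      truth_retained = .data$class_code %in% c("i", "x", "u") &
        .data$len >= 200 & .data$orf_aa <= 120
    )
}
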