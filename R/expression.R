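#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count / (length/1e3) / (total/1e6)`.
#'
#' @param counts raw-count expression tibble (see [expression_matrix()]).
#' @param lengths named numeric vector of transcript lengths in nt, or a data
#'   frame with columns `transcript_id` and `length`.
#' @param totals named numeric vector of mapped reads per sample (names must
#'   cover the sample columns of `counts`).
#' @return expression tibble on the FPKM scale.
#' @export
fpkm <- function(counts, lengths, totals) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$transcript_id)
  }
  vals <- expr_values(counts)
  sc <- colnames(vals)
  miss <- setdiff(rownames(vals), names(lengths))
  if (length(miss)) abort(paste0("no length for transcript(s): ",
                                 paste(utils::head(miss, 5), collapse = ", ")))
  len <- lengths[rownames(vals)]
  bad <- names(len)[len <= 0]
  if (length(bad)) abort(paste0("non-positive length for: ", paste(bad, collapse = ", ")))
  tot <- check_totals(totals, sc)
  out <- sweep(vals, 1, len / 1e3, "/")
  out <- sweep(out, 2, tot / 1e6, "/")
  rebuild_expr(counts, out, "FPKM")
}

#' RPM normalization
#'
#' Reads per million: `count / (total/1e6)`. Used for miRNA read counts and
#' circRNA back-splice junction counts.
#'
#' @inheritParams fpkm
#' @return expression tibble on the RPM scale.
#' @export
rpm <- function(counts, totals) {
  vals <- expr_values(counts)
  tot <- check_totals(totals, colnames(vals))
  rebuild_expr(counts, sweep(vals, 2, tot / 1e6, "/"), "RPM")
}

check_totals <- function(totals, samples) {
  miss <- setdiff(samples, names(totals))
  if (length(miss)) abort(paste0("no library total for sample(s): ",
                                 paste(miss, collapse = ", ")))
  tot <- totals[samples]
  bad <- names(tot)[tot <= 0]
  if (length(bad)) abort(paste0("non-positive library total for: ",
                                paste(bad, collapse = ", ")))
  tot
}

#' Log2 transform after adding a pseudocount of 1
#'
#' @param x expression tibble on the FPKM or RPM scale.
#' @return expression tibble on the `log2p1` scale.
#' @export
log2p1 <- function(x) {
  sc <- expr_scale(x)
  if (is.null(sc) || !sc %in% c("FPKM", "RPM")) {
    abort("log2p1() expects an FPKM- or RPM-scale expression table")
  }
  vals <- expr_values(x)
  if (any(vals < 0)) abort("negative expression values")
  rebuild_expr(x, log2(vals + 1), "log2p1")
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' The p-value is computed from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return one-row tibble with columns `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("Pearson correlation needs at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tibble(r = r, p = pearson_p(r, n), n = n)
}

#' Replicate-reproducibility filter
#'
#' A transcript is retained when the Pearson correlation between its two
#' replicate time courses satisfies `r > r_min` and `p < p_max` (strict, the
#' thresholds used for temporal reproducibility in the source analysis).
#' Transcripts constant in either replicate have an undefined correlation and
#' are dropped with a warning.
#'
#' @param rep_a,rep_b expression tibbles over the same transcripts and time
#'   points (>= 3 time points).
#' @param r_min,p_max correlation and p-value cutoffs.
#' @return tibble with columns `transcript_id`, `r`, `p`, `retained`.
#' @export
reproducibility_filter <- function(rep_a, rep_b, r_min = 0.5, p_max = 0.05) {
  if (!identical(rep_a$transcript_id, rep_b$transcript_id)) {
    abort("replicates must cover the same transcripts in the same order")
  }
  a <- expr_values(rep_a); b <- expr_values(rep_b)
  if (ncol(a) != ncol(b)) abort("replicates must share the same time points")
  if (ncol(a) < 3) abort("reproducibility filter needs at least 3 time points")
  r <- row_pearson(a, b)
  n_const <- sum(is.na(r))
  if (n_const > 0) {
    warn(paste0(n_const, " transcript(s) dropped: constant in a replicate, ",
                "correlation undefined"))
  }
  p <- ifelse(is.na(r), NA_real_, pearson_p(r, ncol(a)))
  tibble(
    transcript_id = rep_a$transcript_id,
    r = r, p = p,
    retained = !is.na(r) & r > r_min & p < p_max
  )
}

#' Class-specific abundance filter
#'
#' Removes transcripts with low expression throughout the time series, using
#' the class-specific rules of the source analysis: circRNA junction
#' counts >= 2, mRNA and lncRNA FPKM >= 1, miRNA RPM >= 1, each required in at
#' least `min_samples` sample (thresholds inclusive).
#'
#' @param exprs named list of expression tibbles, names in
#'   `c("mRNA", "lncRNA", "circRNA", "miRNA")`. Scales must match the class:
#'   FPKM for mRNA/lncRNA, raw counts for circRNA, RPM for miRNA.
#' @param thresholds named numeric vector of per-class thresholds.
#' @param min_samples number of samples in which the threshold must be met.
#' @return tibble with columns `transcript_id`, `rna_class`, `statistic`
#'   (the max over samples), `threshold`, `retained`.
#' @export
abundance_filter <- function(exprs,
                             thresholds = c(mRNA = 1, lncRNA = 1, circRNA = 2, miRNA = 1),
                             min_samples = 1) {
  required_scale <- c(mRNA = "FPKM", lncRNA = "FPKM",
                      circRNA = "raw_count", miRNA = "RPM")
  bad <- setdiff(names(exprs), names(required_scale))
  if (length(bad)) abort(paste0("unknown RNA class(es): ", paste(bad, collapse = ", ")))
  purrr::imap(exprs, function(x, cls) {
    sc <- expr_scale(x)
    if (!identical(sc, required_scale[[cls]])) {
      abort(paste0(cls, " table must be on the ", required_scale[[cls]],
                   " scale, got ", sc %||% "<undeclared>"))
    }
    vals <- expr_values(x)
    n_pass <- rowSums(vals >= thresholds[[cls]])
    tibble(
      transcript_id = x$transcript_id,
      rna_class = cls,
      statistic = unname(apply(vals, 1, max)),
      threshold = unname(thresholds[[cls]]),
      retained = unname(n_pass >= min_samples)
    )
  }) |>
    purrr::list_rbind()
}

#' Stage-wise differential expression t-test
#'
#' Per-transcript two-sample t-test between two sample groups (development
#' stages), Welch by default. A transcript is flagged significant when
#' `p < alpha` (strict, no multiple-testing correction). When both groups are
#' constant the test is undefined; the convention is `p = 1` for equal group
#' means and `p = 0` otherwise, reported with a warning.
#'
#' @param x expression tibble on the log2p1 scale.
#' @param group_a,group_b character vectors of sample column names (>= 2 each).
#' @param alpha significance threshold.
#' @param var_equal use the pooled-variance (Student) test instead of Welch.
#' @return tibble with columns `transcript_id`, `mean_a`, `mean_b`, `t`, `df`,
#'   `p`, `significant`.
#' @export
stage_de_ttest <- function(x, group_a, group_b, alpha = 0.05, var_equal = FALSE) {
  sc <- expr_scale(x)
  if (!is.null(sc) && sc != "log2p1") {
    abort("stage_de_ttest() expects log2-scale values")
  }
  miss <- setdiff(c(group_a, group_b), sample_cols(x))
  if (length(miss)) abort(paste0("unknown sample(s): ", paste(miss, collapse = ", ")))
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  vals <- expr_values(x)
  a <- vals[, group_a, drop = FALSE]
  b <- vals[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df = df)
  degenerate <- se == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " transcript(s) constant in both groups; ",
                "p set to 1 (equal means) or 0 (unequal) by convention"))
    eq <- degenerate & (ma == mb)
    t[degenerate] <- ifelse(eq[degenerate], 0, sign(ma - mb)[degenerate] * Inf)
    p[degenerate] <- ifelse(eq[degenerate], 1, 0)
    df[degenerate] <- NA_real_
  }
  tibble(
    transcript_id = x$transcript_id,
    mean_a = unname(ma), mean_b = unname(mb),
    t = unname(t), df = unname(df), p = unname(p),
    significant = unname(p < alpha)
  )
}

#' Co-expression of exonic circRNAs with their parent genes
#'
#' For each exonic circRNA, the Pearson correlation between its temporal
#' profile and that of its single parent gene; the summary fraction counts
#' circRNAs with `r > r_min` and `p < p_max`. circRNAs whose parent gene is
#' absent from `gene_expr` are skipped with a warning and excluded from the
#' denominator.
#'
#' @param junctions classified junction tibble (see [classify_circ_junctions()])
#'   from which rows with `circ_class == "exonic"` are used.
#' @param circ_expr expression tibble over junction ids.
#' @param gene_expr expression tibble over gene ids.
#' @param r_min,p_max co-expression cutoffs.
#' @return list with `results` (tibble: `junction_id`, `parent_gene`, `r`,
#'   `p`, `coexpressed`) and `fraction` (proportion co-expressed).
#' @export
parent_coexpression <- function(junctions, circ_expr, gene_expr,
                                r_min = 0.5, p_max = 0.05) {
  ec <- dplyr::filter(junctions, .data$circ_class == "exonic")
  ec <- dplyr::filter(ec, .data$junction_id %in% circ_expr$transcript_id)
  missing_parent <- !ec$parent_genes %in% gene_expr$transcript_id
  if (any(missing_parent)) {
    warn(paste0(sum(missing_parent),
                " exonic circRNA(s) skipped: parent gene not in expression table"))
    ec <- ec[!missing_parent, , drop = FALSE]
  }
  if (nrow(ec) == 0) {
    return(list(results = tibble(junction_id = character(), parent_gene = character(),
                                 r = numeric(), p = numeric(), coexpressed = logical()),
                fraction = NA_real_))
  }
  cm <- expr_values(circ_expr)
  gm <- expr_values(gene_expr)
  shared <- intersect(colnames(cm), colnames(gm))
  r <- row_pearson(cm[ec$junction_id, shared, drop = FALSE],
                   gm[ec$parent_genes, shared, drop = FALSE])
  p <- ifelse(is.na(r), NA_real_, pearson_p(r, length(shared)))
  res <- tibble(
    junction_id = ec$junction_id,
    parent_gene = ec$parent_genes,
    r = r, p = p,
    coexpressed = !is.na(r) & r > r_min & p < p_max
  )
  list(results = res, fraction = mean(res$coexpressed))
}
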