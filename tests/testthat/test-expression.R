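test_that("fpkm matches the closed form and validates its inputs", {
  counts <- expression_matrix(
    tibble::tibble(transcript_id = c("t1", "t2"), S1 = c(10, 0), S2 = c(5, 7)),
    "raw_count"
  )
  out <- fpkm(counts, c(t1 = 1000, t2 = 500), c(S1 = 1e6, S2 = 2e6))
  expect_equal(out$S1, c(10, 0))
  expect_equal(expr_scale(out), "FPKM")

  # random matrix against an independent per-cell recomputation
  set.seed(42)
  m <- matrix(rpois(30, 50), 5, 6,
              dimnames = list(paste0("t", 1:5), paste0("S", 1:6)))
  lens <- setNames(sample(200:2000, 5), rownames(m))
  tots <- setNames(sample(1e6:5e6, 6), colnames(m))
  got <- fpkm(expression_matrix(
    dplyr::bind_cols(tibble::tibble(transcript_id = rownames(m)),
                     tibble::as_tibble(m)), "raw_count"), lens, tots)
  for (i in 1:5) for (j in 1:6) {
    expect_equal(as.numeric(got[i, colnames(m)[j]]),
                 m[i, j] / (lens[[i]] / 1e3) / (tots[[j]] / 1e6))
  }
  expect_error(fpkm(counts, c(t1 = 0, t2 = 500), c(S1 = 1e6, S2 = 1e6)), "t1")
  expect_error(fpkm(counts, c(t1 = 10, t2 = 500), c(S1 = 0, S2 = 1e6)), "S1")
})

test_that("rpm scales by library size and conserves exhaustive counts", {
  counts <- expression_matrix(
    tibble::tibble(transcript_id = "j1", S1 = 2), "raw_count")
  expect_equal(rpm(counts, c(S1 = 2e6))$S1, 1)

  # counts covering every read in a sample sum to one million RPM
  full <- expression_matrix(
    tibble::tibble(transcript_id = paste0("t", 1:4),
                   S1 = c(10, 20, 30, 40) * 1e4), "raw_count")
  out <- rpm(full, c(S1 = 1e6))
  expect_equal(sum(out$S1), 1e6)

  # linearity in counts
  doubled <- expression_matrix(
    dplyr::mutate(full, S1 = S1 * 2), "raw_count")
  expect_equal(rpm(doubled, c(S1 = 1e6))$S1, out$S1 * 2)
})

test_that("log2p1 transforms FPKM/RPM scales only", {
  x <- expression_matrix(
    tibble::tibble(transcript_id = c("a", "b", "c"), S1 = c(0, 1, 10)),
    "raw_count")
  expect_error(log2p1(x), "FPKM")
  x_fpkm <- fpkm(x, c(a = 1000, b = 1000, c = 1000), c(S1 = 1e6))
  out <- log2p1(x_fpkm)
  expect_equal(out$S1, log2(c(1, 2, 11)))
  expect_equal(out$S1[3], 3.4594, tolerance = 1e-4)
  expect_equal(expr_scale(out), "log2p1")
})

test_that("pearson_cor agrees with cor.test and rejects degenerate input", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$r, -1)
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(14); y <- rnorm(14)
    ref <- cor.test(x, y)
    got <- pearson_cor(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("reproducibility filter keeps correlated replicates only", {
  set.seed(1)
  prof <- rnorm(14, 5, 2)
  a <- make_expr(list(t1 = prof, t2 = rnorm(14), t3 = rep(2, 14)))
  b <- make_expr(list(t1 = prof, t2 = rnorm(14), t3 = rep(2, 14)))
  expect_warning(res <- reproducibility_filter(a, b), "constant")
  expect_true(res$retained[res$transcript_id == "t1"])
  expect_equal(res$r[res$transcript_id == "t1"], 1)
  expect_false(res$retained[res$transcript_id == "t3"]) # dropped, undefined r

  # a permuted replicate should almost never look reproducible
  kept <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(14, 5, 2)
    ra <- make_expr(list(t = x)); rb <- make_expr(list(t = sample(x)))
    reproducibility_filter(ra, rb)$retained
  }, logical(1))
  expect_lte(mean(kept), 0.10)
})

test_that("abundance filter applies the class-specific rules exactly", {
  # hand-built 12-transcript toy with known pass/fail for every rule
  mrna <- make_expr(list(
    m_pass_edge = c(1, rep(0, 13)),      # FPKM exactly 1 in one sample: kept
    m_fail = rep(0.99, 14),              # below 1 everywhere: removed
    m_pass_high = rep(5, 14)
  ), scale = "FPKM")
  lnc <- make_expr(list(
    l_pass = c(rep(0, 13), 2.5),
    l_fail = rep(0.5, 14)
  ), scale = "FPKM")
  circ <- make_expr(list(
    c_pass_edge = c(2, rep(0, 13)),      # exactly 2 junction reads: kept
    c_fail_one = rep(1, 14),             # never reaches 2: removed
    c_pass = c(rep(0, 10), 7, 0, 0, 0),
    c_fail_zero = rep(0, 14)
  ), scale = "raw_count")
  mir <- make_expr(list(
    r_pass_edge = c(rep(0, 7), 1, rep(0, 6)),
    r_fail = rep(0.99, 14),
    r_pass = rep(3, 14)
  ), scale = "RPM")
  res <- abundance_filter(list(mRNA = mrna, lncRNA = lnc,
                               circRNA = circ, miRNA = mir))
  expect_equal(nrow(res), 12)
  kept <- sort(res$transcript_id[res$retained])
  expect_equal(kept, sort(c("m_pass_edge", "m_pass_high", "l_pass",
                            "c_pass_edge", "c_pass",
                            "r_pass_edge", "r_pass")))
  expect_equal(sum(res$retained), 7)

  # idempotence / order independence: filtering a subset gives the same calls
  res2 <- abundance_filter(list(circRNA = circ))
  expect_equal(res2$retained,
               res$retained[match(res2$transcript_id, res$transcript_id)])
  expect_error(abundance_filter(list(mRNA = circ)), "FPKM")
})

test_that("stage t-test matches t.test, honors conventions, and has power", {
  growth <- paste0("Day", seq(4, 18, 2)); sen <- paste0("Day", seq(20, 30, 2))

  x <- make_expr(list(flat = rep(c(1, 2, 3), length.out = 14)))
  # identical group values -> t = 0, p = 1
  xx <- make_expr(list(t1 = c(1, 2, 3, 1, 2, 3, 1, 2, 1, 2, 3, 1, 2, 3)))
  res <- stage_de_ttest(xx, c("Day4", "Day6", "Day8"), c("Day10", "Day12", "Day14"))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)

  # Welch agreement with stats::t.test on random data
  set.seed(11)
  mat <- lapply(1:20, function(i) rnorm(14, 5))
  names(mat) <- paste0("t", 1:20)
  xr <- make_expr(mat)
  got <- stage_de_ttest(xr, growth, sen)
  vals <- cernaforge:::expr_values(xr)
  for (i in 1:20) {
    ref <- t.test(vals[i, growth], vals[i, sen])
    expect_equal(got$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-12)
  }
  # pooled-variance flag
  gotp <- stage_de_ttest(xr, growth, sen, var_equal = TRUE)
  refp <- t.test(vals[1, growth], vals[1, sen], var.equal = TRUE)
  expect_equal(gotp$p[1], refp$p.value, tolerance = 1e-12)

  # degenerate conventions
  const <- make_expr(list(eq = rep(2, 14),
                          ne = rep(c(1, 5), times = c(8, 6))))
  expect_warning(cres <- stage_de_ttest(const, growth, sen), "convention")
  expect_equal(cres$p, c(1, 0))

  # power: planted 3-sd shift, 8 vs 6 samples, detected in >= 95% of sims
  set.seed(3)
  hits <- vapply(1:200, function(i) {
    y <- c(rnorm(8, 0), rnorm(6, 3))
    e <- make_expr(list(t = y))
    stage_de_ttest(e, growth, sen)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("parent co-expression fraction counts co-expressed ecircRNAs", {
  set.seed(5)
  genes <- lapply(1:20, function(i) rnorm(14, 5))
  names(genes) <- sprintf("G%02d", 1:20)
  gene_expr <- make_expr(genes)
  # first 3 circRNAs duplicate their parent profile, the rest are noise
  circs <- lapply(1:20, function(i) {
    if (i <= 3) genes[[i]] + 0.01 * rnorm(14) else rnorm(14, 2)
  })
  names(circs) <- sprintf("J%02d", 1:20)
  circ_expr <- make_expr(circs)
  junctions <- tibble::tibble(
    junction_id = names(circs),
    circ_class = "exonic",
    parent_genes = names(genes)
  )
  res <- parent_coexpression(junctions, circ_expr, gene_expr)
  expect_equal(res$results$coexpressed[1:3], rep(TRUE, 3))
  expect_equal(res$fraction, mean(res$results$coexpressed))
  expect_equal(sum(res$results$coexpressed[1:3]), 3)

  # all profiles duplicated from parents -> fraction 1
  res_dup <- parent_coexpression(junctions,
                                 make_expr(setNames(genes, names(circs))),
                                 gene_expr)
  expect_equal(res_dup$fraction, 1)

  # missing parent: skipped with warning, excluded from the denominator
  j2 <- dplyr::mutate(junctions, parent_genes = replace(parent_genes, 1, "GX"))
  expect_warning(res_miss <- parent_coexpression(j2, circ_expr, gene_expr),
                 "skipped")
  expect_equal(nrow(res_miss$results), 19)
})

test_that("replicate averaging collapses columns by time point", {
  x <- expression_matrix(
    tibble::tibble(transcript_id = "t1",
                   Day4_R1 = 1, Day4_R2 = 3, Day6_R1 = 2, Day6_R2 = 4),
    "FPKM")
  out <- average_replicates(x)
  expect_equal(sample_cols(out), c("Day4", "Day6"))
  expect_equal(unlist(out[1, c("Day4", "Day6")], use.names = FALSE), c(2, 3))
  expect_equal(expr_scale(out), "FPKM")
})
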