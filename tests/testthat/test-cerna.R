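test_that("shared-miRNA hypergeometric test matches enumeration and theory", {
  expect_equal(hypergeom_shared_test(0, 3, 4, 10), 1) # tail from zero
  expect_equal(hypergeom_shared_test(5, 5, 5, 5), 1)  # forced full overlap
  expect_equal(hypergeom_shared_test(3, 5, 4, 10), 55 / 210)
  expect_equal(hyper_enum_oracle(3, 5, 4, 10), 55 / 210) # oracle agrees

  # symmetry in (K_a, K_b)
  expect_equal(hypergeom_shared_test(2, 7, 3, 20),
               hypergeom_shared_test(2, 3, 7, 20))

  # monotone non-increasing in k, equal to 1 at k = 0
  p <- hypergeom_shared_test(0:4, 6, 4, 12)
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 1)

  expect_error(hypergeom_shared_test(3, 2, 5, 10), "k must lie")
  expect_error(hypergeom_shared_test(1, 11, 5, 10), "exceed N")
})

test_that("pair calling accepts exactly the pairs passing both criteria", {
  # a and b share 3 of 4 miRNAs and co-vary; c widens the universe to 19
  # miRNAs but shares none with them
  tab <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3", "m4", "m1", "m2", "m3", "m5",
                 sprintf("m%02d", 7:20)),
    target_id = c(rep("a", 4), rep("b", 4), rep("c", 14)),
    target_class = "mRNA"
  )
  set.seed(2)
  prof <- rnorm(14, 5, 2)
  expr <- make_expr(list(a = prof, b = prof + rnorm(14, 0, 0.1),
                         c = rnorm(14, 5)))
  pairs <- call_cerna_pairs(tab, expr, keep_rejected = TRUE)
  ab <- pairs[pairs$id_a == "a" & pairs$id_b == "b", ]
  expect_equal(ab$k_shared, 3L)
  expect_equal(ab$K_a, 4L); expect_equal(ab$K_b, 4L)
  expect_equal(ab$N_universe, 19L)
  expect_equal(ab$p_hyper, hyper_enum_oracle(3, 4, 4, 19))
  expect_true(ab$accepted)
  # c shares no miRNA with anyone: never a candidate
  expect_false(any(pairs$id_a == "c" | pairs$id_b == "c"))

  # every accepted pair passes both criteria when rechecked independently
  acc <- call_cerna_pairs(tab, expr)
  for (i in seq_len(nrow(acc))) {
    expect_lt(acc$p_hyper[i], 0.05)
    ref <- cor.test(unlist(expr[expr$transcript_id == acc$id_a[i],
                                sample_cols(expr)]),
                    unlist(expr[expr$transcript_id == acc$id_b[i],
                                sample_cols(expr)]))
    expect_equal(acc$r[i], unname(ref$estimate), tolerance = 1e-12)
    expect_gt(acc$r[i], 0.5)
    expect_lt(acc$p_corr[i], 0.05)
  }

  expect_error(call_cerna_pairs(tab, make_expr(list(a = prof, b = prof))),
               "absent from expression")
})

test_that("candidate enumeration equals an all-pairs brute force", {
  set.seed(13)
  ids <- sprintf("t%02d", 1:12)
  tab <- purrr::map(ids, function(id) {
    tibble::tibble(mirna_id = sample(sprintf("m%02d", 1:10), 3),
                   target_id = id, target_class = "mRNA")
  }) |> purrr::list_rbind()
  expr <- make_expr(setNames(lapply(1:12, function(i) rnorm(14, 5)), ids))
  got <- call_cerna_pairs(tab, expr, keep_rejected = TRUE)

  by_target <- split(tab$mirna_id, tab$target_id)
  n_univ <- dplyr::n_distinct(tab$mirna_id)
  combos <- utils::combn(sort(ids), 2)
  brute <- purrr::map(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    k <- length(intersect(by_target[[a]], by_target[[b]]))
    if (k < 1) return(NULL)
    tibble::tibble(id_a = a, id_b = b, k_shared = k,
                   p_hyper = hyper_enum_oracle(k, 3, 3, n_univ))
  }) |> purrr::list_rbind()
  expect_equal(got[c("id_a", "id_b", "k_shared")],
               brute[c("id_a", "id_b", "k_shared")])
  expect_equal(got$p_hyper, brute$p_hyper, tolerance = 1e-12)

  # accepted set is invariant under input row order
  got2 <- call_cerna_pairs(tab[sample(nrow(tab)), ], expr, keep_rejected = TRUE)
  expect_equal(got, got2)
})

test_that("network assembly builds the documented node and edge sets", {
  pairs <- tibble::tibble(
    id_a = "a", id_b = "b", class_a = "mRNA", class_b = "lncRNA",
    k_shared = 2L, K_a = 2L, K_b = 2L, N_universe = 10L,
    p_hyper = 0.01, r = 0.9, p_corr = 0.001, accepted = TRUE
  )
  tab <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m2", "m3"),
    target_id = c("a", "b", "a", "b", "z"),
    target_class = c("mRNA", "lncRNA", "mRNA", "lncRNA", "mRNA")
  )
  net <- assemble_network(pairs, tab)
  expect_equal(sum(net$nodes$type != "miRNA"), 2)
  expect_equal(sum(net$nodes$type == "miRNA"), 2) # m1, m2 shared; m3 not
  expect_equal(nrow(net$competing), 1)
  expect_equal(nrow(net$regulatory), 4)

  empty <- assemble_network(pairs[0, ], tab)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$competing), 0)
  expect_equal(nrow(empty$regulatory), 0)
})

test_that("network reconstruction matches an independent brute force", {
  ds <- simulate_dataset(tiny_sim_config(seed = 5))
  tab <- ds$targets
  ml <- average_replicates(log2p1(fpkm(ds$counts$mRNA, ds$lengths, ds$totals)))
  ln <- average_replicates(log2p1(fpkm(ds$counts$lncRNA, ds$lengths, ds$totals)))
  ci <- average_replicates(log2p1(rpm(ds$counts$circRNA, ds$totals)))
  expr <- dplyr::bind_rows(ml, ln, ci) |> expression_matrix("log2p1")
  acc <- call_cerna_pairs(tab, expr)
  net <- assemble_network(acc, tab)

  by_target <- split(tab$mirna_id, tab$target_id)
  shared <- sort(unique(unlist(
    purrr::map2(acc$id_a, acc$id_b,
                ~ intersect(by_target[[.x]], by_target[[.y]])))))
  rna_nodes <- sort(unique(c(acc$id_a, acc$id_b)))
  expect_setequal(net$nodes$id[net$nodes$type == "miRNA"], shared)
  expect_setequal(net$nodes$id[net$nodes$type != "miRNA"], rna_nodes)
  reg <- tab[tab$mirna_id %in% shared & tab$target_id %in% rna_nodes, ]
  expect_equal(nrow(net$regulatory), nrow(dplyr::distinct(
    reg[c("mirna_id", "target_id")])))
})

test_that("stage networks use only each stage's expression columns", {
  growth <- paste0("Day", seq(4, 18, 2)); sen <- paste0("Day", seq(20, 30, 2))
  tab <- tibble::tibble(
    mirna_id = c(rep(c("m1", "m2", "m3", "m4"), 2), sprintf("m%02d", 5:20)),
    target_id = c(rep(c("a", "b"), each = 4), rep("z", 16)),
    target_class = "mRNA"
  )
  set.seed(8)
  base <- rnorm(8, 5, 2)
  # correlated during growth, anti-correlated during senescence
  a <- c(base, c(1, 2, 3, 4, 5, 6))
  b <- c(base + rnorm(8, 0, 0.05), c(6, 5, 4, 3, 2, 1))
  expr <- make_expr(list(a = a, b = b, z = rnorm(14, 3)))
  nets <- stage_networks(tab, expr,
                         list(growth = growth, senescence = sen))
  expect_equal(nrow(nets$growth$competing), 1)
  expect_equal(nrow(nets$senescence$competing), 0)
  expect_equal(nets$growth$stage, "growth")

  # identical profiles in both stages appear in both networks
  expr2 <- make_expr(list(a = a, b = a + rnorm(14, 0, 0.01), z = rnorm(14, 3)))
  nets2 <- stage_networks(tab, expr2,
                          list(growth = growth, senescence = sen))
  expect_equal(nrow(nets2$growth$competing), 1)
  expect_equal(nrow(nets2$senescence$competing), 1)

  expect_error(stage_networks(tab, expr, list(growth = growth[1:2],
                                              senescence = sen)),
               "fewer than 3")
})

test_that("network export writes nodes, edges and GraphML", {
  pairs <- tibble::tibble(
    id_a = "a", id_b = "b", class_a = "mRNA", class_b = "mRNA",
    k_shared = 1L, K_a = 1L, K_b = 1L, N_universe = 5L,
    p_hyper = 0.04, r = 0.8, p_corr = 0.01, accepted = TRUE
  )
  tab <- tibble::tibble(mirna_id = "m1", target_id = c("a", "b"),
                        target_class = "mRNA")
  net <- assemble_network(pairs, tab)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[3], format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
})
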