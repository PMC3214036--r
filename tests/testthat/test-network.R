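edge_df <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    protein_a = vapply(pairs, `[[`, character(1), 1),
    protein_b = vapply(pairs, `[[`, character(1), 2)
  )
}

test_that("network construction drops self-edges and collapses duplicates", {
  net <- build_network(edge_df(c("A", "B"), c("B", "A"), c("C", "C")))
  expect_identical(igraph::ecount(net), 1)
  expect_setequal(igraph::V(net)$name, c("A", "B"))

  empty <- build_network(edge_df())
  expect_identical(igraph::vcount(empty), 0)

  withr::local_seed(21)
  raw <- edge_df(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"), c("I", "J"),
                 c("K", "L"), c("M", "N"), c("O", "P"), c("Q", "R"), c("S", "T"),
                 c("A", "C"), c("B", "D"), c("E", "G"), c("F", "H"), c("I", "K"),
                 c("B", "A"), c("D", "C"), c("E", "F"),      # 3 duplicates
                 c("A", "A"), c("Q", "Q"))                   # 2 self-pairs
  expect_identical(igraph::ecount(build_network(raw)), 15)
})

test_that("category subnetworks follow the one-or-both and both rules", {
  net <- build_network(edge_df(c("A", "B"), c("B", "C")))
  one <- category_subnetwork(net, "A", mode = "one_or_both")
  expect_identical(igraph::ecount(one), 1)
  expect_setequal(igraph::V(one)$name, c("A", "B"))
  expect_identical(igraph::ecount(category_subnetwork(net, "A", mode = "both")), 0)

  one_ab <- category_subnetwork(net, c("A", "B"), "one_or_both")
  both_ab <- category_subnetwork(net, c("A", "B"), "both")
  expect_identical(igraph::ecount(one_ab), 2)
  expect_identical(igraph::ecount(both_ab), 1)
  # both-mode is a subgraph of one-or-both mode
  expect_true(all(igraph::V(both_ab)$name %in% igraph::V(one_ab)$name))
  expect_error(category_subnetwork(net, "A", mode = "either"), "one_or_both")
})

test_that("network summaries match closed forms on tiny graphs", {
  tri <- summarize_network(build_network(
    edge_df(c("A", "B"), c("B", "C"), c("C", "A"))))
  expect_identical(tri$proteins, 3L)
  expect_identical(tri$interactions, 3L)
  expect_identical(tri$max_degree, 2L)
  expect_equal(tri$avg_degree, 2)
  expect_identical(tri$components, 1L)
  expect_equal(tri$lcc_protein_pct, 100)
  expect_equal(tri$lcc_interaction_pct, 100)

  two <- summarize_network(build_network(
    edge_df(c("A", "B"), c("B", "C"), c("C", "D"), c("E", "F"))))
  expect_identical(two$proteins, 6L)
  expect_identical(two$interactions, 4L)
  expect_identical(two$components, 2L)
  expect_equal(two$lcc_protein_pct, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(two$lcc_interaction_pct, 75)

  zero <- summarize_network(build_network(edge_df()))
  expect_identical(zero$proteins, 0L)
  expect_identical(zero$components, 0L)
})

test_that("summaries equal the brute-force BFS oracle on random graphs", {
  withr::local_seed(23)
  for (rep in 1:40) {
    raw <- random_edge_df(n_nodes = sample(5:60, 1), n_pairs = sample(3:120, 1))
    got <- summarize_network(build_network(tibble::as_tibble(raw)))
    want <- oracle_network_summary(raw)
    expect_identical(got$proteins, as.integer(want$proteins))
    expect_identical(got$interactions, as.integer(want$interactions))
    expect_identical(got$max_degree, want$max_degree)
    expect_equal(got$avg_degree, want$avg_degree, tolerance = 1e-12)
    expect_identical(got$components, as.integer(want$components))
    expect_equal(got$lcc_protein_pct, want$lcc_protein_pct, tolerance = 1e-12)
    expect_equal(got$lcc_interaction_pct, want$lcc_interaction_pct, tolerance = 1e-12)
    expect_equal(got$lcc_avg_degree, want$lcc_avg_degree, tolerance = 1e-12)
  }
})

test_that("degree sequences support member restriction", {
  net <- build_network(edge_df(c("A", "B"), c("B", "C")))
  expect_identical(degree_sequence(net), c(1, 2, 1)[order(c("A", "B", "C"))])
  expect_identical(degree_sequence(net, members = "B"), 2)
  withr::local_seed(29)
  raw <- random_edge_df(30, 60)
  net2 <- build_network(tibble::as_tibble(raw))
  deg <- degree_sequence(net2)
  # degree sum equals twice the edge count
  expect_identical(sum(deg), 2 * igraph::ecount(net2))
})

test_that("per-group summary rows match independent recomputation", {
  ds <- simulate_dataset(synthetic_config(n_genes = 400), seed = 5)
  cl <- classify_dataset(ds)
  net <- build_network(ds$ppi)
  tab2 <- network_group_summary(cl, net)
  expect_identical(tab2$group, c("DL", "DV", "L", "V", "DU"))
  for (g in c("DL", "L", "DU")) {
    members <- cl$gene_id[cl$group == g]
    el <- igraph::as_edgelist(net)
    keep <- el[, 1] %in% members | el[, 2] %in% members
    want <- oracle_network_summary(data.frame(a = el[keep, 1], b = el[keep, 2]))
    row <- tab2[tab2$group == g, ]
    expect_identical(row$proteins, as.integer(want$proteins))
    expect_identical(row$interactions, as.integer(want$interactions))
    expect_equal(row$avg_degree, floor(10 * want$avg_degree + 0.5) / 10)
  }
  # a group with no members yields a zero row
  cl_none <- cl
  cl_none$group[cl_none$group == "DV"] <- "DU"
  row0 <- network_group_summary(cl_none, net)
  expect_identical(row0$proteins[row0$group == "DV"], 0L)
  expect_identical(row0$interactions[row0$group == "DV"], 0L)
})

test_that("both-mode edge lists are subsets of the one-or-both subnetworks", {
  ds <- simulate_dataset(synthetic_config(n_genes = 300), seed = 8)
  cl <- classify_dataset(ds)
  net <- build_network(ds$ppi)
  els <- group_edge_lists(cl, net)
  expect_named(els, c("DL", "DV", "L", "V", "DU"))
  for (g in names(els)) {
    members <- cl$gene_id[cl$group == g]
    el <- els[[g]]
    if (nrow(el) > 0) {
      expect_true(all(el$protein_a %in% members))
      expect_true(all(el$protein_b %in% members))
    }
    one <- category_subnetwork(net, members, "one_or_both")
    both <- category_subnetwork(net, members, "both")
    expect_lte(igraph::ecount(both), igraph::ecount(one))
    expect_true(all(igraph::V(both)$name %in% igraph::V(one)$name))
  }
})
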