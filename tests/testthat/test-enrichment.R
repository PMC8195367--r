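test_that("hypergeometric enrichment matches exact enumeration and edge cases", {
  bg <- paste0("g", 1:10)
  ann <- paste0("g", 1:4)
  members <- c("g1", "g2", "g3", "g5", "g6")  # overlap 3
  res <- hypergeometric_enrichment(members, ann, bg)
  expect_equal(res$overlap, 3)
  # exact enumeration over all C(10,5) draws
  draws <- utils::combn(bg, 5)
  tail_p <- mean(apply(draws, 2, function(s) length(intersect(s, ann)) >= 3))
  expect_equal(res$p_value, tail_p, tolerance = 1e-12)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (3 / 5) / (4 / 10))

  # zero overlap -> right tail at 0 is 1
  res0 <- hypergeometric_enrichment(c("g9", "g10"), c("g1"), bg)
  expect_equal(res0$p_value, 1)
  # annotation covering the background
  resb <- hypergeometric_enrichment(c("g1", "g2"), bg, bg)
  expect_equal(resb$p_value, 1)
  expect_equal(resb$fold_enrichment, 1)
  expect_error(hypergeometric_enrichment(c("zz"), ann, bg), "background")
  # monotone decreasing p in the overlap at fixed margins
  ps <- vapply(0:4, function(x) phyper(x - 1, 4, 6, 5, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("edge enrichment: density folds, empty sets, and the exact null", {
  bg <- paste0("n", 1:8)
  # first 14 of 28 pairs -> background density 0.5; they include the full
  # clique on n1..n4, whose internal density 1.0 gives fold 2
  all_pairs <- t(utils::combn(bg, 2))
  edges <- tibble::tibble(from = all_pairs[1:14, 1], to = all_pairs[1:14, 2])
  res <- edge_enrichment(bg[1:4], edges, bg, mode = "gene_gene")
  expect_equal(res$overlap, 6)
  expect_equal(res$fold_enrichment, 2)

  # node set spanning no edges: observed 0, right-tail p = 1
  none <- edge_enrichment(bg[7:8], edges[0, ], bg, mode = "gene_gene")
  expect_equal(none$overlap, 0)
  expect_equal(none$p_value, 1)

  # exact node-set enumeration on a 12-node graph vs an independent oracle
  nodes <- paste0("v", 1:12)
  g <- random_graph(nodes, 18, seed = 31)
  nset <- nodes[c(1, 3, 5, 7, 9)]
  res_exact <- edge_enrichment(nset, g, nodes, mode = "gene_gene", null = "exact")
  obs <- sum(g$from %in% nset & g$to %in% nset)
  oracle <- mean(apply(utils::combn(nodes, 5), 2, function(s)
    sum(g$from %in% s & g$to %in% s) >= obs))
  expect_equal(res_exact$p_value, oracle, tolerance = 1e-12)
  # hypergeometric approximation agrees with the exact null on this graph
  res_hyper <- edge_enrichment(nset, g, nodes, mode = "gene_gene")
  expect_lt(abs(res_hyper$p_value - oracle), 0.15)
})

test_that("mirna-gene edge enrichment counts ordered-pair slots", {
  bgm <- paste0("m", 1:4); bgg <- paste0("g", 1:6)
  edges <- tibble::tibble(from = c("m1", "m1", "m2", "m3"),
                          to = c("g1", "g2", "g1", "g5"))
  res <- edge_enrichment(list(mirnas = c("m1", "m2"), genes = c("g1", "g2")),
                         edges, list(mirnas = bgm, genes = bgg),
                         mode = "mirna_gene")
  expect_equal(res$overlap, 3)          # m1-g1, m1-g2, m2-g1
  expect_equal(res$set_size, 4)         # 2 x 2 slots
  expect_equal(res$background_size, 24) # 4 x 6 slots
  expect_equal(res$fold_enrichment, (3 / 4) / (4 / 24))
  expect_error(edge_enrichment(list(mirnas = "m9", genes = "g1"),
                               edges, list(mirnas = bgm, genes = bgg),
                               mode = "mirna_gene"), "background")
})

test_that("degree-aware test is seed-stable, calibrated on regular graphs, and punishes hubs", {
  # ring lattice: every node has degree 2, so binning is vacuous
  nodes <- paste0("r", 1:20)
  ring <- tibble::tibble(from = nodes, to = nodes[c(2:20, 1)])
  nset <- nodes[c(1, 2, 3, 10, 15)]
  r1 <- degree_aware_edge_test(nset, ring, nodes, n_perm = 400, seed = 9)
  r2 <- degree_aware_edge_test(nset, ring, nodes, n_perm = 400, seed = 9)
  expect_identical(attr(r1, "null_scores"), attr(r2, "null_scores"))
  # plain uniform permutation null on a regular graph: build by binning into 1 bin
  r3 <- degree_aware_edge_test(nset, ring, nodes, n_perm = 400, seed = 10, bins = 1)
  expect_lt(abs(r1$p_value - r3$p_value), 0.1)

  # star-like graph: a module of hubs is unremarkable once degree is conditioned on
  hubs <- paste0("h", 1:4); leaves <- paste0("l", 1:40)
  star <- tibble::tibble(
    from = c(rep(hubs, each = 10), "h1", "h2", "h3"),
    to = c(paste0("l", 1:40), "h2", "h3", "h4"))
  all_nodes <- c(hubs, leaves)
  naive <- edge_enrichment(hubs, star, all_nodes, mode = "gene_gene")
  aware <- suppressWarnings(
    degree_aware_edge_test(hubs, star, all_nodes, n_perm = 500, seed = 11))
  expect_gt(aware$p_value, naive$p_value)
})

test_that("family cooperativity finds shared families and is minimal-p on packed modules", {
  fams <- list(mir17 = paste0("f", 1:5), solo1 = "x1", solo2 = "x2")
  universe <- c(paste0("f", 1:5), paste0("x", 1:518))
  res <- family_cooperativity(paste0("f", 1:5), fams, universe,
                              n_perm = 1000, seed = 12)
  expect_equal(res$max_in_family, 5)
  expect_true(res$cooperative)
  expect_equal(res$top_family, "mir17")
  expect_equal(res$p_value, 1 / 1001)
  # singleton families: statistic 1, not cooperative
  res1 <- family_cooperativity(c("x1", "x2", "x3"),
                               list(a = "x1", b = "x2"), universe,
                               n_perm = 100, seed = 13)
  expect_equal(res1$max_in_family, 1)
  expect_false(res1$cooperative)
  r1 <- family_cooperativity(c("f1", "f2", "x1"), fams, universe, n_perm = 200, seed = 14)
  r2 <- family_cooperativity(c("f1", "f2", "x1"), fams, universe, n_perm = 200, seed = 14)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(family_cooperativity(paste0("f", 1:9), fams, paste0("f", 1:5),
                                    n_perm = 10, seed = 1), "universe")
})

test_that("three-layer network extraction classifies layers and picks the right component", {
  net <- extract_three_layer_network(
    genes = c("g1", "g2", "g3"), mirnas = "m1",
    mirna_gene_edges = tibble::tibble(from = "m1", to = "g1"),
    gene_gene_edges = tibble::tibble(from = "g1", to = "g2"))
  expect_equal(net$mirnas, "m1")
  expect_equal(net$direct_genes, "g1")
  expect_equal(net$indirect_genes, "g2")
  expect_equal(unname(net$counts["edges"]), 2L)

  # two equal-size components: deterministic pick by smallest node label
  net2 <- extract_three_layer_network(
    genes = c("a1", "a2", "b1", "b2"), mirnas = character(0),
    mirna_gene_edges = tibble::tibble(from = character(0), to = character(0)),
    gene_gene_edges = tibble::tibble(from = c("b1", "a1"), to = c("b2", "a2")))
  expect_setequal(net2$indirect_genes, c("a1", "a2"))

  # empty graph
  net0 <- extract_three_layer_network(
    genes = "g1", mirnas = "m1",
    mirna_gene_edges = tibble::tibble(from = character(0), to = character(0)),
    gene_gene_edges = tibble::tibble(from = character(0), to = character(0)))
  expect_equal(unname(net0$counts), c(0L, 0L, 0L, 0L))
})

test_that("component membership agrees with a breadth-first search oracle", {
  set.seed(33)
  genes <- paste0("g", 1:15); mirnas <- paste0("m", 1:4)
  mg <- tibble::tibble(from = sample(mirnas, 6, TRUE), to = sample(genes, 6, TRUE))
  gg <- random_graph(genes, 8, seed = 34)
  net <- extract_three_layer_network(genes, mirnas, mg, gg)

  # BFS oracle over the same restricted mixed graph
  edges <- rbind(as.matrix(unique(mg)), as.matrix(gg))
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  comp_of <- function(start) {
    seen <- start; queue <- start
    while (length(queue) > 0) {
      nxt <- setdiff(unique(unlist(adj[queue])), seen)
      seen <- c(seen, nxt); queue <- nxt
    }
    sort(seen)
  }
  nodes_in_net <- sort(c(net$mirnas, net$direct_genes, net$indirect_genes))
  expect_identical(comp_of(nodes_in_net[1]), nodes_in_net)
  # every miRNA kept has an outgoing edge
  for (m in net$mirnas)
    expect_true(m %in% net$edges$from[net$edges$type == "mirna_gene"])
})
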