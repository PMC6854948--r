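test_that("node degrees match the incidence-count oracle", {
  tri <- mk_net(c("A", "A", "B"), c("B", "C", "C"))
  expect_true(all(node_degree(tri) == 2))

  star <- mk_net(rep("C0", 4), paste0("L", 1:4))
  d <- node_degree(star)
  expect_equal(unname(d["C0"]), 4)
  expect_true(all(d[paste0("L", 1:4)] == 1))

  pr <- rg_pairs(100, 0.04, 61)
  net <- mk_net(pr$from, pr$to)
  e <- tidy(net)
  ref <- table(c(e$from, e$to))
  d2 <- node_degree(net)
  expect_equal(unname(d2[names(ref)]), as.vector(ref))
})

test_that("Brandes betweenness matches hand values on path and star", {
  p3 <- mk_net(c("A", "B"), c("B", "C"))
  b <- betweenness_brandes(p3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  star <- mk_net(rep("C0", 4), paste0("L", 1:4))
  bs <- betweenness_brandes(star)
  expect_equal(unname(bs["C0"]), choose(4, 2))
  expect_true(all(bs[paste0("L", 1:4)] == 0))
})

test_that("betweenness equals exhaustive shortest-path enumeration on small graphs", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pr <- rg_pairs(n, stats::runif(1, 0.3, 0.7), seed + 100)
    net <- mk_net(pr$from, pr$to)
    A <- adj_matrix(net)
    oracle <- oracle_betweenness(A)
    got <- betweenness_brandes(net)
    expect_equal(unname(got[rownames(A)]), unname(oracle$node),
                 tolerance = 1e-9)
    expect_equal(edge_btw_as_matrix(net), oracle$edge, tolerance = 1e-9)
  }
})

test_that("betweenness agrees with igraph's implementation on a larger graph", {
  pr <- rg_pairs(80, 0.05, 77)
  net <- mk_net(pr$from, pr$to)
  ours <- betweenness_brandes(net)
  ref <- igraph::betweenness(net$graph)
  expect_equal(unname(ours[names(ref)]), unname(ref), tolerance = 1e-9)
  ours_e <- stonenet::edge_betweenness(net)
  ref_e <- igraph::edge_betweenness(net$graph)
  expect_equal(ours_e$betweenness, ref_e, tolerance = 1e-9)
})

test_that("edge betweenness on trees equals the n1 x n2 split formula", {
  p3 <- mk_net(c("A", "B"), c("B", "C"))
  expect_true(all(stonenet::edge_betweenness(p3)$betweenness == 2))
  single <- mk_net("A", "B")
  expect_equal(stonenet::edge_betweenness(single)$betweenness, 1)

  for (seed in 1:8) {
    n <- sample(5:20, 1)
    pr <- rtree_pairs(n, seed + 200)
    net <- mk_net(pr$from, pr$to)
    eb <- stonenet::edge_betweenness(net)
    e <- tidy(net)
    for (i in seq_len(nrow(eb))) {
      # component size on the 'from' side after deleting the edge
      keep <- !(e$from == eb$from[i] & e$to == eb$to[i])
      reach <- eb$from[i]
      repeat {
        nxt <- unique(c(e$to[keep & e$from %in% reach],
                        e$from[keep & e$to %in% reach]))
        new <- setdiff(nxt, reach)
        if (length(new) == 0) break
        reach <- c(reach, new)
      }
      n1 <- length(reach)
      expect_equal(eb$betweenness[i], n1 * (n - n1))
    }
    # degree-1 nodes of a tree have zero node betweenness
    b <- betweenness_brandes(net)
    leaves <- names(which(node_degree(net) == 1))
    expect_true(all(b[leaves] == 0))
  }
})

test_that("composite rank averages per-metric descending ranks", {
  # star with sum-aggregated edge betweenness: center tops all three metrics
  star <- mk_net(rep("C0", 5), paste0("L", 1:5))
  ct <- composite_hub_rank(centrality_table(star, edge_agg = "sum"))
  expect_equal(ct$composite_rank[ct$symbol == "C0"], 1)

  # cycle: full symmetry, every composite rank is (N+1)/2
  n <- 6
  cyc <- mk_net(nsym(1:n), nsym(c(2:n, 1)))
  ctc <- composite_hub_rank(centrality_table(cyc))
  expect_true(all(ctc$composite_rank == (n + 1) / 2))

  # independent rank recomputation on a 100-node graph
  pr <- rg_pairs(100, 0.05, 91)
  net <- mk_net(pr$from, pr$to)
  ct2 <- composite_hub_rank(centrality_table(net))
  ref <- (rank(-ct2$degree) + rank(-ct2$betweenness) +
            rank(-ct2$edge_btw_score)) / 3
  expect_equal(ct2$composite_rank, ref)
  expect_true(all(ct2$composite_rank >= 1 &
                    ct2$composite_rank <= nrow(ct2)))
})

test_that("backbone extraction takes ceil(fraction * N) hubs deterministically", {
  net <- generate_interactome(360, "preferential_attachment", m = 2,
                              seed = 33)
  dn <- build_disease_network(net, node_names(net))
  expect_equal(igraph::vcount(dn$graph), 340 + 20)  # PA graph is connected
  # trim to exactly 340 nodes to exercise the printed-scale arithmetic
  dn340 <- build_disease_network(
    net, sort(node_names(net))[1:340])
  bb <- extract_backbone(dn340, fraction = 0.10)
  expect_length(bb$hub_symbols, ceiling(0.10 * igraph::vcount(dn340$graph)))

  full <- extract_backbone(dn, fraction = 1)
  expect_setequal(full$hub_symbols, node_names(dn))
  expect_equal(igraph::ecount(full$graph), igraph::ecount(dn$graph))

  # determinism
  again <- extract_backbone(dn340, fraction = 0.10)
  expect_identical(again$hub_symbols, bb$hub_symbols)

  # ceil property across fractions
  for (f in c(0.01, 0.1, 0.25, 0.5, 1)) {
    expect_length(extract_backbone(dn, fraction = f)$hub_symbols,
                  ceiling(f * igraph::vcount(dn$graph)))
  }
  expect_error(extract_backbone(dn, fraction = 0), "fraction")
})

test_that("centralities and hub membership are insertion-order invariant", {
  pr <- rg_pairs(50, 0.08, 13)
  net1 <- mk_net(pr$from, pr$to)
  set.seed(14)
  perm <- sample(length(pr$from))
  flip <- stats::runif(length(perm)) < 0.5
  f2 <- ifelse(flip, pr$to, pr$from)[perm]
  t2 <- ifelse(flip, pr$from, pr$to)[perm]
  net2 <- mk_net(f2, t2)
  ct1 <- dplyr::arrange(composite_hub_rank(centrality_table(net1)), symbol)
  ct2 <- dplyr::arrange(composite_hub_rank(centrality_table(net2)), symbol)
  expect_equal(ct1, ct2)
  b1 <- extract_backbone(build_disease_network(net1, node_names(net1)), 0.2)
  b2 <- extract_backbone(build_disease_network(net2, node_names(net2)), 0.2)
  expect_identical(b1$hub_symbols, b2$hub_symbols)
})
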