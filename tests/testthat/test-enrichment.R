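test_that("overlap margins match set arithmetic", {
  ot <- overlap_table(c("A", "B"), c("B", "C"), c("A", "B", "C", "D"))
  expect_equal(ot, list(k = 1L, K = 2L, n = 2L, N = 4L),
               ignore_attr = TRUE)
  expect_equal(overlap_table("A", c("B", "C"), c("A", "B", "C"))$k, 0L)
  expect_error(overlap_table("A", "B", character(0)), "empty background")

  set.seed(71)
  bg <- sprintf("G%03d", 1:60)
  for (i in 1:100) {
    q <- sample(bg, sample(1:20, 1))
    term <- sample(sprintf("G%03d", 1:80), sample(1:30, 1))
    ot <- overlap_table(q, term, bg)
    expect_equal(ot$k, length(intersect(q, intersect(term, bg))))
    expect_equal(ot$K, length(intersect(term, bg)))
    expect_equal(ot$n, length(q))
    expect_equal(ot$N, 60)
  }
})

test_that("fisher and EASE p-values match exhaustive hypergeometric enumeration", {
  expect_equal(enrichment_pvalue(4, 5, 4, 10, "fisher"),
               choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(enrichment_pvalue(4, 5, 4, 10, "ease"), 55 / 210)
  expect_equal(enrichment_pvalue(0, 5, 4, 10, "fisher"), 1)
  expect_equal(enrichment_pvalue(0, 5, 4, 10, "ease"), 1)
  expect_error(enrichment_pvalue(5, 4, 5, 10), "margins")

  # EASE is never smaller than Fisher
  set.seed(72)
  for (i in 1:200) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    f <- enrichment_pvalue(k, K, n, N, "fisher")
    e <- enrichment_pvalue(k, K, n, N, "ease")
    expect_gte(e, f)
    expect_equal(f, oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("p-values are invariant under permutation of background labels", {
  set.seed(73)
  bg <- sprintf("G%03d", 1:50)
  q <- sample(bg, 10); term <- sample(bg, 15)
  p1 <- do.call(enrichment_pvalue, c(overlap_table(q, term, bg),
                                     mode = "ease"))
  relab <- stats::setNames(sample(sprintf("H%03d", 1:50)), bg)
  p2 <- do.call(enrichment_pvalue,
                c(overlap_table(relab[q], relab[term], unname(relab)),
                  mode = "ease"))
  expect_identical(p1, p2)
})

test_that("BH adjustment: standard step-up and DAVID-compatible p*m/rank", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), m = 3), rep(0.03, 3))
  expect_equal(bh_adjust(0.2, m = 1), 0.2)
  # david_compat drops the step-up minimum: rows need not be monotone
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03), m = 3, david_compat = TRUE),
               c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.010, 0.011), m = 10, david_compat = TRUE),
               c(0.10, 0.055))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")

  set.seed(74)
  for (i in 1:20) {
    p <- stats::runif(sample(2:15, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= 0))
    expect_true(all(adj <= 1))
  }
})

test_that("percent-scale FDR follows 100 * (1 - (1 - p)^m)", {
  expect_equal(fdr_percent(1e-9, 14.7), 100 * 14.7 * 1e-9,
               tolerance = 1e-6)
  expect_equal(fdr_percent(1, 5), 100)
  expect_equal(fdr_percent(8.45e-6, 14.7), 100 * (1 - (1 - 8.45e-6)^14.7))
  expect_equal(fdr_percent(8.45e-6, 14.7), 0.012422, tolerance = 1e-4)
})

test_that("category enrichment reproduces the published Count/% semantics", {
  query <- kidney_stone_backbone_genes()
  expect_length(query, 31)
  gs <- kidney_stone_gene_sets()
  bg <- unique(c(query, unlist(gs$BP$genes)))
  res <- enrich_category(query, gs$BP, bg)
  pf <- res[res$term_id == "GO:0006457", ]
  expect_equal(pf$count, 6)
  expect_equal(pf$percent, 100 * 6 / 31)
  expect_equal(round(pf$percent, 4), 19.3548)
  expect_identical(pf$genes[[1]],
                   sort(c("HSP90AB1", "P4HB", "HSP90B1", "HSP90AA1",
                          "APCS", "CALR")))
  # rows sorted ascending by p; counts equal printed gene-list lengths
  expect_true(all(diff(res$p_value) >= 0))
  fx <- kidney_stone_go_fixture()
  fx_bp <- fx[fx$category == "BP", ]
  expect_equal(res$count[match(fx_bp$term_id, res$term_id)],
               lengths(fx_bp$genes))
})

test_that("disjoint queries give empty results and planted terms rank first", {
  gs <- new_test_collection(list(T1 = c("A", "B"), T2 = c("C", "D")))
  res <- enrich_category(c("X", "Y"), gs, c("A", "B", "C", "D", "X", "Y"))
  expect_equal(nrow(res), 0)

  net <- generate_interactome(300, "preferential_attachment", m = 2,
                              seed = 81)
  pl <- plant_candidate_module(net, module_size = 15, internal_p = 0.8,
                               n_noise = 0, n_unmapped = 0, seed = 82)
  ann <- generate_annotation_db(pl$net, n_terms = 50,
                                planted = list(list(
                                  genes = pl$truth$planted_module,
                                  jaccard = 0.9)),
                                seed = 83)
  bg <- node_names(pl$net)
  res2 <- enrich_category(pl$truth$planted_module, ann$gene_sets, bg)
  expect_equal(res2$term_id[1], "PLANTED1")
})

test_that("correction denominator counts tested terms, not reported rows", {
  gs <- new_test_collection(list(T1 = c("A", "B"), T2 = c("C", "D"),
                                 T3 = c("E", "F"), T4 = c("Z9", "Z8")))
  bg <- c("A", "B", "C", "D", "E", "F", "Q")
  res <- enrich_category(c("A", "B", "C"), gs, bg)
  # T4 has no background gene -> m = 3; T3 tested but k = 0 -> not reported
  expect_equal(attr(res, "m"), 3)
  expect_true(all(res$term_id %in% c("T1", "T2")))
  expect_equal(res$benjamini,
               bh_adjust(c(enrichment_pvalue(2, 2, 3, 7, "ease"),
                           enrichment_pvalue(1, 2, 3, 7, "ease"),
                           1), m = 3)[1:2],
               tolerance = 1e-12)
  expect_error(enrich_category(c("A", "B"), gs, "A"), "smaller")
})
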