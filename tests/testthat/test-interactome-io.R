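test_that("TSV reader drops self-loops and duplicate edges, counting both", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "B\tC", "C\tC"), path)
  net <- read_edge_list(path, "tsv")
  expect_setequal(node_names(net), c("A", "B", "C"))
  expect_equal(nrow(tidy(net)), 2)
  expect_equal(net$metadata$duplicates_dropped, 1)
  expect_equal(net$metadata$self_loops_dropped, 1)
})

test_that("SIF rows fan out to one edge per listed partner", {
  path <- tempfile(fileext = ".sif")
  writeLines("A\tpp\tB\tC", path)
  net <- read_edge_list(path, "sif")
  e <- tidy(net)
  expect_setequal(paste(e$from, e$to), c("A B", "A C"))
})

test_that("symbols are uppercased and mixed-case duplicates collapse", {
  net <- as_interactome(data.frame(a = c("tp53", "TP53"),
                                   b = c("mdm2", "Mdm2")))
  expect_setequal(node_names(net), c("TP53", "MDM2"))
  expect_equal(nrow(tidy(net)), 1)
  expect_equal(net$metadata$duplicates_dropped, 1)
})

test_that("write/read round trips reproduce node and edge sets", {
  # 5-node path
  path5 <- mk_net(nsym(1:4), nsym(2:5))
  # random graphs, all three formats
  for (seed in 1:3) {
    pr <- rg_pairs(40, 0.08, seed)
    net <- mk_net(pr$from, pr$to)
    for (fmt in c("tsv", "sif", "graphml")) {
      f <- tempfile(fileext = paste0(".", fmt))
      write_network(net, f, fmt)
      back <- if (fmt == "graphml") read_graphml(f)
              else read_edge_list(f, fmt)
      expect_setequal(node_names(back), node_names(net))
      e1 <- dplyr::arrange(tidy(net), from, to)
      e2 <- dplyr::arrange(tidy(back), from, to)
      expect_equal(e2, e1)
      unlink(f)
    }
  }
  f <- tempfile(fileext = ".tsv")
  write_network(path5, f, "tsv")
  expect_identical(sort(node_names(read_edge_list(f, "tsv"))),
                   sort(node_names(path5)))
  # SIF keeps isolated nodes through the round trip
  iso <- mk_net("A", "B", isolates = "Z")
  f2 <- tempfile(fileext = ".sif")
  write_network(iso, f2, "sif")
  expect_setequal(node_names(read_edge_list(f2, "sif")), c("A", "B", "Z"))
})

test_that("reader invariants hold on fuzzed edge lists", {
  for (seed in 1:10) {
    set.seed(seed)
    n_rows <- sample(3:30, 1)
    syms <- c("a", "B", "cC", "D", "e1")
    rows <- paste(sample(syms, n_rows, TRUE), sample(syms, n_rows, TRUE),
                  sep = "\t")
    path <- tempfile(fileext = ".tsv")
    writeLines(rows, path)
    net <- read_edge_list(path, "tsv")
    e <- tidy(net)
    expect_true(all(e$from != e$to))                      # no self-loops
    expect_false(any(duplicated(paste(e$from, e$to))))    # no duplicates
    expect_true(all(c(e$from, e$to) %in% node_names(net)))
    expect_identical(node_names(net), toupper(node_names(net)))
    unlink(path)
  }
})

test_that("malformed and empty network files raise informative errors", {
  p1 <- tempfile(); writeLines(c("A\tB", "LONESYMBOL"), p1)
  expect_error(read_edge_list(p1, "tsv"), "line 2")
  p2 <- tempfile(); writeLines(c("A pp B", "A pp"), p2)
  expect_error(read_edge_list(p2, "sif"), "line 2")
  p3 <- tempfile(); file.create(p3)
  expect_error(read_edge_list(p3, "tsv"), "empty")
  expect_error(write_network(structure(list(graph = igraph::make_empty_graph()),
                                       class = "interactome"),
                             tempfile(), "tsv"),
               "empty")
})

test_that("normalize_symbols collapses synonyms and reports unmapped names", {
  map <- c(GRP78 = "HSPA5", BIP = "HSPA5")
  out <- normalize_symbols(c("grp78", "HSPA5", "Bip"), map)
  expect_identical(out$symbols, "HSPA5")
  expect_identical(out$unmapped, character(0))

  out2 <- normalize_symbols("FOO1", character(0))
  expect_identical(out2$symbols, character(0))
  expect_identical(out2$unmapped, "FOO1")

  # re-normalizing already-canonical symbols is the identity
  canon <- c("TP53", "MDM2", "HSPA5")
  again <- normalize_symbols(canon, map)
  expect_identical(again$symbols, "HSPA5")
  full_map <- stats::setNames(canon, canon)
  expect_identical(normalize_symbols(canon, full_map)$symbols, canon)
})

test_that("a proteomics + text-mining merge with synonym collisions dedups correctly", {
  # 775 canonical proteomics names; 112 text-mining names of which 48 are
  # synonyms of proteomics entries -> 887 raw names, 839 unique symbols
  prot <- sprintf("C%04d", 1:775)
  tm_canon <- sprintf("C%04d", 776:839)            # 64 genuinely new
  tm_syn <- sprintf("ALIAS%02d", 1:48)             # 48 colliding synonyms
  map <- stats::setNames(c(prot, tm_canon, sprintf("C%04d", 1:48)),
                         c(prot, tm_canon, tm_syn))
  raw <- c(prot, tm_canon, tm_syn)
  expect_length(raw, 887)
  out <- normalize_symbols(raw, map)
  expect_identical(out$unmapped, character(0))
  expect_length(out$symbols, length(unique(unname(map[toupper(raw)]))))
  expect_length(out$symbols, 839)
})

test_that("GMT parsing uppercases, dedups and validates", {
  p <- tempfile(fileext = ".gmt")
  writeLines("T1\tdesc\ta\tb\tb", p)
  gs <- read_gmt(p)
  expect_identical(gs$genes[[1]], c("A", "B"))

  p_empty <- tempfile(fileext = ".gmt"); file.create(p_empty)
  expect_warning(gs0 <- read_gmt(p_empty), "empty")
  expect_equal(nrow(gs0), 0)

  p_dup <- tempfile(fileext = ".gmt")
  writeLines(c("T1\td\tA", "T1\td\tB"), p_dup)
  expect_error(read_gmt(p_dup), "duplicate")

  p_short <- tempfile(fileext = ".gmt")
  writeLines(c("T1\td\tA", "T2\tdesc"), p_short)
  expect_error(read_gmt(p_short), "line 2")
})

test_that("the packaged backbone ORA fixture parses to 36 terms over 4 categories", {
  gs <- kidney_stone_gene_sets()
  expect_named(gs, c("BP", "CC", "MF", "KEGG"))
  expect_equal(sum(vapply(gs, nrow, 0L)), 36)
  expect_equal(vapply(gs, nrow, 0L),
               c(BP = 8L, CC = 13L, MF = 6L, KEGG = 9L))
  # GMT round trip
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs$BP, f)
  back <- read_gmt(f, "BP")
  expect_equal(back$term_id, gs$BP$term_id)
  expect_equal(back$genes, gs$BP$genes)
})

test_that("GMT reader agrees with fgsea's parser on the fixture", {
  skip_if_not_installed("fgsea")
  f <- system.file("extdata", "kidney_stone_bp.gmt", package = "stonenet")
  ours <- read_gmt(f, "BP")
  theirs <- fgsea::gmtPathways(f)
  expect_setequal(ours$term_id, names(theirs))
  for (id in ours$term_id) {
    expect_setequal(ours$genes[[which(ours$term_id == id)]], theirs[[id]])
  }
})
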