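# Test helpers: small graph builders and independent brute-force oracles.
# Oracles deliberately share no code with the package implementation.

nsym <- function(i) sprintf("N%03d", i)

# interactome from explicit endpoint vectors; isolates via a SIF tempfile
mk_net <- function(from, to, isolates = character()) {
  if (length(isolates) == 0) {
    return(as_interactome(data.frame(from = from, to = to)))
  }
  path <- tempfile(fileext = ".sif")
  on.exit(unlink(path))
  writeLines(c(paste(from, "pp", to, sep = "\t"), isolates), path)
  read_edge_list(path, "sif")
}

# Erdos-Renyi-style edge pairs on n labelled nodes (guaranteed >= 1 edge)
rg_pairs <- function(n, p, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  list(from = nsym(idx[keep, 1]), to = nsym(idx[keep, 2]))
}

# random recursive tree: node i attaches to a uniform earlier node
rtree_pairs <- function(n, seed) {
  set.seed(seed)
  to <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
  list(from = nsym(2:n), to = nsym(to))
}

adj_matrix <- function(net) {
  nodes <- sort(node_names(net))
  e <- tidy(net)
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(e$from, e$to)] <- 1L
  A[cbind(e$to, e$from)] <- 1L
  A
}

# exhaustive shortest-path enumeration oracle for node and edge betweenness
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bc <- stats::setNames(numeric(n), rownames(A))
  eb <- matrix(0, n, n, dimnames = dimnames(A))
  enum_paths <- function(s, t) {
    paths <- list()
    rec <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (w in which(A[v, ] == 1L)) {
        if (!(w %in% path)) rec(w, c(path, w))
      }
    }
    rec(s, s)
    paths
  }
  if (n < 2) return(list(node = bc, edge = eb))
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enum_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      sp <- paths[lens == min(lens)]
      w <- 1 / length(sp)
      for (p in sp) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + w
        for (i in seq_len(length(p) - 1)) {
          a <- min(p[i], p[i + 1]); b <- max(p[i], p[i + 1])
          eb[a, b] <- eb[a, b] + w
        }
      }
    }
  }
  list(node = bc, edge = eb)
}

# compare edge_betweenness() tibble against an oracle edge matrix
edge_btw_as_matrix <- function(net) {
  nodes <- sort(node_names(net))
  eb <- stonenet::edge_betweenness(net)
  M <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  M[cbind(eb$from, eb$to)] <- eb$betweenness
  M
}

# exhaustive hypergeometric upper-tail by direct choose() summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# connected-component sizes by plain union-find on the edge table
oracle_lcc_size <- function(net, symbols) {
  parent <- stats::setNames(symbols, symbols)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  e <- tidy(net)
  inset <- e$from %in% symbols & e$to %in% symbols
  for (i in which(inset)) {
    a <- find(e$from[i]); b <- find(e$to[i])
    if (a != b) parent[[a]] <- b
  }
  if (length(symbols) == 0) return(0L)
  max(table(vapply(symbols, find, character(1))))
}

oracle_edge_count <- function(net, symbols) {
  e <- tidy(net)
  sum(e$from %in% symbols & e$to %in% symbols)
}

# build a gene_set_collection from a named list of gene vectors, via GMT
new_test_collection <- function(sets, category = "TEST") {
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, paste(id, "description"), sets[[id]]), collapse = "\t")
  }, character(1)), path)
  read_gmt(path, category)
}
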