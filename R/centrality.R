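# Centrality measures and hub-backbone extraction.
#
# Node betweenness and edge betweenness are computed with the Brandes
# accumulation scheme on unweighted BFS shortest paths: for each source, path
# counts sigma are accumulated forward and dependencies delta backward; the
# per-source contributions are summed and halved so each unordered pair is
# counted once. Values are left unnormalized — the hub ranking only uses
# ranks, which are normalization-invariant.

#' Node degrees
#' @param graph An `interactome`, `disease_network` or igraph.
#' @return Named integer vector of incident-edge counts.
#' @export
node_degree <- function(graph) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) == 0) abort("empty graph")
  igraph::degree(g)
}

# Shared Brandes pass. Returns list(node = named numeric, edge = numeric per
# edge id in the graph's edge order).
brandes_pass <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  nodes <- igraph::V(g)$name
  bc <- numeric(n)
  ebc <- numeric(m)
  if (n == 0) abort("empty graph")
  if (m == 0) {
    return(list(node = stats::setNames(bc, nodes), edge = ebc))
  }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  # adjacency: neighbor ids and the id of the connecting edge
  nbr <- vector("list", n)
  eid <- vector("list", n)
  for (e in seq_len(m)) {
    u <- ends[e, 1]; v <- ends[e, 2]
    nbr[[u]] <- c(nbr[[u]], v); eid[[u]] <- c(eid[[u]], e)
    nbr[[v]] <- c(nbr[[v]], u); eid[[v]] <- c(eid[[v]], e)
  }
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv <- dist[v]
      for (w in nbr[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (i in seq.int(tail, 1L)) {
      w <- queue[i]
      nw <- nbr[[w]]; ew <- eid[[w]]
      pred <- which(dist[nw] == dist[w] - 1L)
      if (length(pred)) {
        contrib <- sigma[nw[pred]] / sigma[w] * (1 + delta[w])
        ebc[ew[pred]] <- ebc[ew[pred]] + contrib
        for (j in seq_along(pred)) {
          delta[nw[pred[j]]] <- delta[nw[pred[j]]] + contrib[j]
        }
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  list(node = stats::setNames(bc / 2, nodes), edge = ebc / 2)
}

#' Brandes betweenness centrality
#'
#' For each node v, the sum over unordered pairs s != t (both distinct from
#' v) of the fraction of s-t shortest paths passing through v. Disconnected
#' pairs contribute zero; values are unnormalized.
#'
#' @inheritParams node_degree
#' @return Named numeric vector.
#' @export
betweenness_brandes <- function(graph) {
  brandes_pass(as_igraph(graph))$node
}

#' Edge betweenness centrality
#'
#' Per edge, the sum over unordered node pairs of the fraction of shortest
#' paths using that edge. For a tree edge splitting the tree into components
#' of sizes n1 and n2 the value is n1 * n2.
#'
#' @inheritParams node_degree
#' @return A tibble with columns `from`, `to` (from < to) and `betweenness`.
#' @export
edge_betweenness <- function(graph) {
  g <- as_igraph(graph)
  res <- brandes_pass(g)
  if (igraph::ecount(g) == 0) {
    return(tibble(from = character(0), to = character(0),
                  betweenness = numeric(0)))
  }
  e <- igraph::as_data_frame(g, what = "edges")
  tibble(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
         betweenness = res$edge)
}

#' Per-node centrality table
#'
#' Computes the three hub metrics — node degree, Brandes betweenness, and an
#' edge-betweenness score lifted to nodes — for every node. The lift is the
#' maximum edge betweenness over a node's incident edges by default (a node
#' sitting on one critical bridge ranks as a hub); `edge_agg = "sum"`
#' aggregates over all incident edges instead.
#'
#' @inheritParams node_degree
#' @param edge_agg `"max"` (default) or `"sum"`: how incident edge
#'   betweenness is aggregated per node.
#' @return A tibble with columns `symbol`, `degree`, `betweenness`,
#'   `edge_btw_score`.
#' @export
centrality_table <- function(graph, edge_agg = c("max", "sum")) {
  edge_agg <- match.arg(edge_agg)
  g <- as_igraph(graph)
  deg <- node_degree(g)
  res <- brandes_pass(g)
  nodes <- igraph::V(g)$name
  score <- stats::setNames(numeric(length(nodes)), nodes)
  if (igraph::ecount(g) > 0) {
    e <- igraph::as_data_frame(g, what = "edges")
    long <- tibble(symbol = c(e$from, e$to), val = rep(res$edge, 2))
    agg <- long |>
      dplyr::group_by(.data$symbol) |>
      dplyr::summarise(score = if (edge_agg == "max") max(.data$val)
                               else sum(.data$val),
                       .groups = "drop")
    score[agg$symbol] <- agg$score
  }
  tibble(symbol = nodes,
         degree = as.integer(deg[nodes]),
         betweenness = unname(res$node[nodes]),
         edge_btw_score = unname(score[nodes]))
}

#' Composite hub rank from the three centrality metrics
#'
#' Each metric is ranked descending (rank 1 = most central) with average
#' ranks over ties; the composite is the arithmetic mean of the three ranks,
#' so lower means more hub-like. Ranks are used rather than raw values
#' because the three metrics live on incomparable scales.
#'
#' @param ct A centrality table from [centrality_table()].
#' @return `ct` with added columns `rank_degree`, `rank_betweenness`,
#'   `rank_edge_btw`, `composite_rank`.
#' @export
composite_hub_rank <- function(ct) {
  stopifnot(all(c("symbol", "degree", "betweenness", "edge_btw_score")
                %in% names(ct)))
  desc_rank <- function(x) rank(-x, ties.method = "average")
  ct |>
    dplyr::mutate(
      rank_degree = desc_rank(.data$degree),
      rank_betweenness = desc_rank(.data$betweenness),
      rank_edge_btw = desc_rank(.data$edge_btw_score),
      composite_rank = (.data$rank_degree + .data$rank_betweenness +
                          .data$rank_edge_btw) / 3
    )
}

#' Extract the hub backbone of a disease network
#'
#' Ranks nodes by the composite of degree, betweenness and edge-betweenness
#' ranks and keeps the top `ceiling(fraction * N)` as hubs (ties at the cut
#' broken by lexicographic symbol order); the backbone is the subgraph
#' induced on the hubs, retaining hubs that end up isolated. Centralities are
#' computed on the disease network itself, so the backbone is derived from
#' the primary disease network, not the full interactome.
#'
#' @param disease_net A `disease_network` (or any network object).
#' @param fraction Hub fraction in (0, 1], default 0.10.
#' @param edge_agg Edge-betweenness lift, see [centrality_table()].
#' @return A `backbone_result`: list with `hub_symbols` (ordered by
#'   composite rank), `graph`, `fraction` and `centrality` (full table with
#'   ranks and `is_hub`).
#' @export
extract_backbone <- function(disease_net, fraction = 0.10,
                             edge_agg = c("max", "sum")) {
  edge_agg <- match.arg(edge_agg)
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  g <- as_igraph(disease_net)
  ct <- composite_hub_rank(centrality_table(g, edge_agg = edge_agg))
  n <- nrow(ct)
  n_hubs <- as.integer(ceiling(fraction * n))
  ord <- order(ct$composite_rank, ct$symbol)
  hubs <- ct$symbol[ord][seq_len(n_hubs)]
  ct$is_hub <- ct$symbol %in% hubs
  backbone <- igraph::induced_subgraph(g, hubs)
  structure(
    list(hub_symbols = hubs, graph = backbone, fraction = fraction,
         edge_agg = edge_agg, centrality = ct),
    class = "backbone_result"
  )
}

#' @export
print.backbone_result <- function(x, ...) {
  cat(sprintf(
    "<backbone_result> %d hubs (top %.0f%% by composite centrality rank), %d edges\n",
    length(x$hub_symbols), 100 * x$fraction, igraph::ecount(x$graph)))
  invisible(x)
}

#' @export
tidy.backbone_result <- function(x, ...) {
  dplyr::arrange(x$centrality, .data$composite_rank, .data$symbol)
}

#' @export
glance.backbone_result <- function(x, ...) {
  tibble(n_hubs = length(x$hub_symbols),
         n_backbone_edges = igraph::ecount(x$graph),
         fraction = x$fraction,
         n_nodes_ranked = nrow(x$centrality))
}

#' @rdname extract_backbone
#' @param object A `backbone_result`.
#' @param ... Ignored.
#' @export
autoplot.backbone_result <- function(object, ...) {
  ct <- tidy(object)
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$composite_rank,
                                   y = .data$betweenness,
                                   size = .data$degree,
                                   colour = .data$is_hub)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "composite hub rank (lower = more hub-like)",
                  y = "betweenness centrality", colour = "hub",
                  size = "degree") +
    ggplot2::theme_minimal()
}
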