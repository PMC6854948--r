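# Disease-network construction and the permutation connectivity test.
#
# The test asks whether mapped candidates are more interconnected in the PPI
# interactome than equally sized random gene sets: the observed connectivity
# statistic is compared against n_perm draws of |candidates| nodes from the
# full node universe, and the empirical p-value uses the +1 pseudocount so it
# is never exactly zero.

#' Build the candidate-induced disease subnetwork
#'
#' Induces the subgraph of the interactome on the mapped candidate symbols
#' and removes degree-0 nodes (candidates with no interaction partner among
#' the candidates), recording them as `dropped_isolates`.
#'
#' @param net An `interactome`.
#' @param mapped_symbols Character vector of candidate symbols, all present
#'   in `net` (see [map_to_interactome()]).
#' @return A `disease_network`: list with `graph` (igraph), `dropped_isolates`
#'   and `parent_name`.
#' @export
build_disease_network <- function(net, mapped_symbols) {
  g <- as_igraph(net)
  mapped_symbols <- unique(mapped_symbols)
  missing <- setdiff(mapped_symbols, igraph::V(g)$name)
  if (length(missing) > 0) {
    abort(sprintf("symbols not in interactome: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  sub <- igraph::induced_subgraph(g, mapped_symbols)
  deg <- igraph::degree(sub)
  isolates <- sort(names(deg)[deg == 0])
  if (length(isolates) == length(mapped_symbols)) {
    abort("all candidates are isolated in the interactome")
  }
  sub <- igraph::delete_vertices(sub, isolates)
  structure(
    list(graph = sub, dropped_isolates = isolates,
         parent_name = if (inherits(net, "interactome")) net$name else NA),
    class = "disease_network"
  )
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> %d nodes, %d edges (%d isolated candidates dropped)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$dropped_isolates)))
  invisible(x)
}

#' @export
tidy.disease_network <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  tibble(from = pmin(e$from, e$to), to = pmax(e$from, e$to))
}

#' @export
glance.disease_network <- function(x, ...) {
  tibble(n_nodes = igraph::vcount(x$graph),
         n_edges = igraph::ecount(x$graph),
         n_isolates_dropped = length(x$dropped_isolates))
}

#' Connectivity statistic of a node set within a network
#'
#' `edge_count` is the number of interactome edges with both endpoints in the
#' set (internal edge density, the most direct reading of "significantly
#' linked"); `lcc_size` is the node count of the largest connected component
#' of the induced subgraph.
#'
#' @param net An `interactome` (or igraph).
#' @param symbol_set Non-empty character vector of node symbols in `net`.
#' @param statistic `"edge_count"` (default) or `"lcc_size"`.
#' @return A single number.
#' @export
connectivity_statistic <- function(net, symbol_set,
                                   statistic = c("edge_count", "lcc_size")) {
  statistic <- match.arg(statistic)
  g <- as_igraph(net)
  symbol_set <- unique(symbol_set)
  if (length(symbol_set) == 0) abort("empty symbol set")
  if (!all(symbol_set %in% igraph::V(g)$name)) {
    abort("symbol_set contains nodes not in the network")
  }
  if (statistic == "edge_count") {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    inset <- logical(igraph::vcount(g))
    inset[match(symbol_set, igraph::V(g)$name)] <- TRUE
    sum(inset[ends[, 1]] & inset[ends[, 2]])
  } else {
    sub <- igraph::induced_subgraph(g, symbol_set)
    if (igraph::vcount(sub) == 0) 0L else max(igraph::components(sub)$csize)
  }
}

#' Permutation test of candidate-set connectivity
#'
#' Draws `n_perm` random node sets of size `|symbol_set|` from the full
#' interactome node universe (uniformly without replacement, or stratified
#' within equal-frequency degree bins when `degree_matched = TRUE`), computes
#' the connectivity statistic for each, and reports the empirical p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. With the +1 pseudocount the
#' smallest attainable p is `1/(n_perm+1)`, matching the convention of
#' reporting "P < 0.001" at n = 1000 permutations rather than p = 0.
#'
#' @param net An `interactome`.
#' @param symbol_set Candidate symbols, all present in `net`.
#' @param n_perm Number of permutations (default 1000).
#' @param statistic Connectivity statistic, see [connectivity_statistic()].
#' @param degree_matched Stratify null draws by degree bin?
#' @param bins Number of equal-frequency degree bins (default 10).
#' @param seed Required integer RNG seed; recorded in the result.
#' @param keep_draws Keep the drawn node sets (list of character vectors)?
#' @return A `permutation_result` with `observed`, `null_values`, `p_value`
#'   and the echoed configuration.
#' @export
permutation_test <- function(net, symbol_set, n_perm = 1000,
                             statistic = c("edge_count", "lcc_size"),
                             degree_matched = FALSE, bins = 10,
                             seed, keep_draws = FALSE) {
  statistic <- match.arg(statistic)
  if (missing(seed) || is.null(seed)) abort("an RNG seed is required")
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (bins < 1) abort("bins must be >= 1")
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  symbol_set <- unique(symbol_set)
  k <- length(symbol_set)
  if (k == 0) abort("empty symbol set")
  if (!all(symbol_set %in% nodes)) {
    abort("symbol_set contains nodes not in the network")
  }
  if (degree_matched && bins > 1 && k == length(nodes)) {
    abort("degenerate degree bins: symbol_set equals the whole node universe")
  }

  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  ef <- ends[, 1]; et <- ends[, 2]
  n_nodes <- length(nodes)
  set_idx <- match(symbol_set, nodes)

  stat_fun <- if (statistic == "edge_count") {
    function(idx) {
      inset <- logical(n_nodes); inset[idx] <- TRUE
      sum(inset[ef] & inset[et])
    }
  } else {
    function(idx) {
      sub <- igraph::induced_subgraph(g, idx)
      if (igraph::vcount(sub) == 0) 0L else max(igraph::components(sub)$csize)
    }
  }
  observed <- stat_fun(set_idx)

  if (degree_matched && bins > 1) {
    deg <- igraph::degree(g)
    bin <- dplyr::ntile(rank(deg, ties.method = "first"), bins)
    bin_members <- split(seq_len(n_nodes), bin)
    need <- table(factor(bin[set_idx], levels = names(bin_members)))
    draw_fun <- function() {
      unlist(purrr::imap(bin_members, function(members, b) {
        nb <- need[[b]]
        if (nb == 0) integer(0)
        else members[sample.int(length(members), nb)]
      }), use.names = FALSE)
    }
  } else {
    draw_fun <- function() sample.int(n_nodes, k)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_values <- numeric(n_perm)
  draws <- if (keep_draws) vector("list", n_perm) else NULL
  for (i in seq_len(n_perm)) {
    idx <- draw_fun()
    null_values[i] <- stat_fun(idx)
    if (keep_draws) draws[[i]] <- nodes[idx]
  }
  p_value <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  structure(
    list(observed = observed, null_values = null_values, p_value = p_value,
         draws = draws,
         config = list(n_perm = n_perm, statistic = statistic,
                       degree_matched = degree_matched, bins = bins,
                       seed = seed, set_size = k)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<permutation_result> %s = %g for %d candidates; p = %.4g (n_perm = %d%s)\n",
    cfg$statistic, x$observed, cfg$set_size, x$p_value, cfg$n_perm,
    if (cfg$degree_matched) sprintf(", degree-matched in %d bins", cfg$bins)
    else ""))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_along(x$null_values), null_value = x$null_values)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(
    statistic = x$config$statistic,
    observed = x$observed,
    null_mean = mean(x$null_values),
    null_sd = stats::sd(x$null_values),
    p_value = x$p_value,
    n_perm = x$config$n_perm,
    set_size = x$config$set_size,
    degree_matched = x$config$degree_matched,
    seed = x$config$seed
  )
}

#' @rdname permutation_test
#' @param object A `permutation_result`.
#' @param ... Ignored.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = sprintf("null %s", object$config$statistic),
      y = "permutations",
      title = sprintf("observed = %g, p = %.3g", object$observed,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}
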