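#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# ---- interactome class -------------------------------------------------

#' Construct an interactome from an edge table
#'
#' An interactome is the full undirected protein-protein interaction (PPI)
#' network: the symbol universe onto which disease candidates are mapped and
#' from which permutation nulls are drawn. Gene symbols are uppercased at
#' ingestion; self-loops and duplicate (unordered) edges are dropped, counted
#' and recorded in the object's metadata.
#'
#' @param x A data frame whose first two columns are interaction partners
#'   (gene symbols). Extra columns are ignored.
#' @param name Free-text name for the network.
#' @param source Provenance string stored in metadata (e.g. a file path).
#' @return An `interactome` object wrapping a simple undirected
#'   \pkg{igraph} graph with `$metadata` parse statistics.
#' @examples
#' net <- as_interactome(data.frame(a = c("a", "b"), b = c("b", "c")))
#' glance(net)
#' @export
as_interactome <- function(x, name = "interactome", source = NA_character_) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) {
    abort("edge table needs at least two columns (interaction partners)")
  }
  interactome_from_pairs(as.character(x[[1]]), as.character(x[[2]]),
                         name = name, source = source)
}

interactome_from_pairs <- function(from, to, name, source = NA_character_,
                                   extra_nodes = character()) {
  from <- toupper(trimws(from))
  to <- toupper(trimws(to))
  extra_nodes <- toupper(trimws(extra_nodes))
  if (any(!nzchar(from)) || any(!nzchar(to)) || any(!nzchar(extra_nodes))) {
    abort("empty gene symbol in edge list")
  }
  is_loop <- from == to
  nodes <- sort(unique(c(from, to, extra_nodes)))
  from <- from[!is_loop]
  to <- to[!is_loop]
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup]),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  new_interactome(g, name = name, metadata = list(
    source = source,
    self_loops_dropped = sum(is_loop),
    duplicates_dropped = sum(dup)
  ))
}

new_interactome <- function(graph, name = "interactome", metadata = list()) {
  stopifnot(igraph::is_igraph(graph))
  obj <- structure(
    list(graph = graph, name = name, metadata = metadata),
    class = "interactome"
  )
  validate_interactome(obj)
  obj
}

validate_interactome <- function(net) {
  g <- net$graph
  if (igraph::is_directed(g)) abort("interactome graph must be undirected")
  if (igraph::any_loop(g)) abort("interactome graph must have no self-loops")
  if (igraph::any_multiple(g)) abort("interactome graph must be simple")
  nm <- igraph::V(g)$name
  if (is.null(nm) || any(!nzchar(nm)) || any(nm != toupper(nm))) {
    abort("node symbols must be non-empty uppercase strings")
  }
  invisible(net)
}

#' Node symbols of a network object
#' @param net An `interactome`, `disease_network` or `backbone_result`.
#' @return Character vector of gene symbols.
#' @export
node_names <- function(net) {
  igraph::V(as_igraph(net))$name
}

as_igraph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  net$graph
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %s: %d nodes, %d edges\n",
              x$name, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  md <- x$metadata
  if (length(md)) {
    cat(sprintf("  source: %s | self-loops dropped: %s | duplicates dropped: %s\n",
                md$source %||% NA, md$self_loops_dropped %||% 0,
                md$duplicates_dropped %||% 0))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.interactome <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  tibble(from = pmin(e$from, e$to), to = pmax(e$from, e$to))
}

#' @export
glance.interactome <- function(x, ...) {
  tibble(
    name = x$name,
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    self_loops_dropped = x$metadata$self_loops_dropped %||% 0L,
    duplicates_dropped = x$metadata$duplicates_dropped %||% 0L
  )
}

# ---- readers -----------------------------------------------------------

#' Read a network edge list (TSV or SIF)
#'
#' TSV rows are `A<TAB>B` (extra columns ignored, no header). SIF rows are
#' `A rel B [B2 ...]`, fanning out to one edge per listed partner; a
#' single-symbol SIF row declares an isolated node. Self-loops and duplicate
#' edges are dropped and counted in the returned object's metadata.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"sif"`.
#' @param name Network name; defaults to the file name.
#' @return An [as_interactome()] object.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) abort(sprintf("empty network file: %s", path))
  name <- name %||% basename(path)
  idx <- which(keep)
  from <- character(0); to <- character(0); isolates <- character(0)
  if (format == "tsv") {
    for (i in idx) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      f <- trimws(f)
      if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
        abort(sprintf("malformed TSV edge row at line %d of %s", i, path))
      }
      from <- c(from, f[1]); to <- c(to, f[2])
    }
  } else {
    for (i in idx) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) == 1) {
        isolates <- c(isolates, f[1])
      } else if (length(f) >= 3) {
        from <- c(from, rep(f[1], length(f) - 2))
        to <- c(to, f[-(1:2)])
      } else {
        abort(sprintf("malformed SIF row at line %d of %s", i, path))
      }
    }
  }
  interactome_from_pairs(from, to, name = name, source = path,
                         extra_nodes = isolates)
}

#' Read a GraphML network
#'
#' @inheritParams read_edge_list
#' @return An interactome; node symbols are uppercased and the graph is
#'   simplified (loops/multi-edges dropped and counted).
#' @export
read_graphml <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  if (nrow(e) == 0 && igraph::vcount(g) == 0) {
    abort(sprintf("empty network file: %s", path))
  }
  interactome_from_pairs(e$from, e$to, name = name %||% basename(path),
                         source = path,
                         extra_nodes = igraph::V(g)$name)
}

# ---- writers -----------------------------------------------------------

#' Write a network to TSV, SIF or GraphML
#'
#' SIF output emits one `A pp B` row per edge (plus bare-symbol rows for
#' isolated nodes) so that a write/read round trip reproduces the network
#' exactly; GraphML output carries any per-node attributes supplied via
#' `node_attrs` (e.g. degree, betweenness, composite_rank, is_hub) and loads
#' directly into Cytoscape.
#'
#' @param net An `interactome`, `disease_network` or `backbone_result`.
#' @param path Output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param node_attrs Optional data frame with a `symbol` column plus numeric
#'   or logical attribute columns, attached to GraphML nodes.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) abort("cannot write an empty network")
  e <- igraph::as_data_frame(g, what = "edges")
  if (format == "tsv") {
    writeLines(paste(e$from, e$to, sep = "\t"), path)
  } else if (format == "sif") {
    rows <- paste(e$from, "pp", e$to, sep = "\t")
    iso <- setdiff(igraph::V(g)$name, unique(c(e$from, e$to)))
    writeLines(c(rows, iso), path)
  } else {
    if (!is.null(node_attrs)) {
      stopifnot("symbol" %in% names(node_attrs))
      ord <- match(igraph::V(g)$name, node_attrs$symbol)
      for (col in setdiff(names(node_attrs), "symbol")) {
        val <- node_attrs[[col]][ord]
        if (is.logical(val)) val <- as.integer(val)
        g <- igraph::set_vertex_attr(g, col, value = val)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# ---- symbol normalization ----------------------------------------------

#' Read a symbol map (raw name -> canonical symbol)
#'
#' Two-column TSV, no header: raw name, canonical gene symbol. Both sides are
#' uppercased; a raw name may appear at most once.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (names = raw, values = canonical).
#' @export
read_symbol_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) abort("symbol map must have two columns: raw, canonical")
  as_symbol_map(stats::setNames(df[[2]], df[[1]]))
}

as_symbol_map <- function(map) {
  if (length(map) == 0) return(stats::setNames(character(0), character(0)))
  raw <- toupper(trimws(names(map)))
  canon <- toupper(trimws(unname(map)))
  if (anyDuplicated(raw)) {
    abort("a raw name appears more than once in the symbol map")
  }
  stats::setNames(canon, raw)
}

#' Normalize raw protein names to canonical gene symbols
#'
#' Mirrors the name-unification step applied before candidate merging: each
#' raw name is looked up (case-insensitively) in the map; names equal to a
#' canonical symbol map to themselves; anything else is reported as unmapped,
#' never silently dropped. The output is deduplicated preserving first-seen
#' order, so synonyms collapsing onto one symbol yield a single entry.
#'
#' @param names Character vector of raw protein/gene names.
#' @param symbol_map Named character vector (raw -> canonical) or a
#'   two-column data frame, as from [read_symbol_map()].
#' @return A list with `symbols` (canonical, deduplicated, first-seen order)
#'   and `unmapped` (raw names with no mapping).
#' @export
normalize_symbols <- function(names, symbol_map) {
  if (is.data.frame(symbol_map)) {
    symbol_map <- stats::setNames(as.character(symbol_map[[2]]),
                                  as.character(symbol_map[[1]]))
  }
  map <- as_symbol_map(symbol_map)
  up <- toupper(trimws(names))
  hit <- map[up]
  canon_self <- up %in% unname(map)
  out <- ifelse(!is.na(hit), hit, ifelse(canon_self, up, NA_character_))
  unmapped <- names[is.na(out)]
  symbols <- unname(out[!is.na(out)])
  list(symbols = symbols[!duplicated(symbols)], unmapped = unname(unmapped))
}

# ---- GMT gene sets -----------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT: tab-separated rows `term_id<TAB>description<TAB>gene...`.
#' Member symbols are uppercased and deduplicated per term.
#'
#' @param path Path to the GMT file.
#' @param category Category label attached to the collection (e.g. `"BP"`,
#'   `"CC"`, `"MF"`, `"KEGG"`).
#' @return A `gene_set_collection`: a tibble with columns `term_id`,
#'   `term_name` and a list-column `genes`, carrying a `category` attribute.
#' @export
read_gmt <- function(path, category = NA_character_) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    warn(sprintf("empty GMT file: %s", path))
    return(new_gene_set_collection(
      tibble(term_id = character(0), term_name = character(0),
             genes = list()), category))
  }
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3 || length(genes) == 0) {
      abort(sprintf("GMT row with fewer than 3 columns at line %d of %s",
                    i, path))
    }
    list(term_id = f[1], term_name = f[2], genes = genes[!duplicated(genes)])
  })
  ids <- vapply(rows, `[[`, "", "term_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate term id in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  new_gene_set_collection(
    tibble(term_id = ids,
           term_name = vapply(rows, `[[`, "", "term_name"),
           genes = lapply(rows, `[[`, "genes")),
    category
  )
}

new_gene_set_collection <- function(tbl, category = NA_character_) {
  stopifnot(all(c("term_id", "term_name", "genes") %in% names(tbl)))
  structure(tbl, category = category,
            class = c("gene_set_collection", class(tibble())))
}

#' Write a gene-set collection to GMT
#' @param gs A `gene_set_collection` (or tibble with `term_id`, `term_name`,
#'   list-column `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  rows <- vapply(seq_len(nrow(gs)), function(i) {
    paste(c(gs$term_id[i], gs$term_name[i], gs$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
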