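# Synthetic interactomes, candidate lists and annotation databases with
# serialized ground truth, so every pipeline stage can be exercised and
# benchmarked without access to licensed PPI or annotation resources.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(code)
}

synthetic_symbols <- function(n) {
  sprintf("G%04d", seq_len(n))
}

#' Generate a synthetic interactome
#'
#' `preferential_attachment` grows a Barabasi-Albert graph (each new node
#' attaches `m` edges preferentially to high-degree nodes), giving the
#' heavy-tailed degree distribution typical of PPI networks;
#' `configuration` realizes a supplied degree sequence as a connected simple
#' graph. In both cases the largest connected component is returned as a
#' simple graph with synthetic symbols `G0001 ...`.
#'
#' @param n_nodes Number of nodes (>= 10).
#' @param model `"preferential_attachment"` or `"configuration"`.
#' @param m Edges attached per new node (preferential attachment), default 2.
#' @param degree_seq Integer degree sequence (configuration model).
#' @param seed Integer RNG seed; output is reproducible per seed.
#' @return An `interactome`.
#' @export
generate_interactome <- function(n_nodes,
                                 model = c("preferential_attachment",
                                           "configuration"),
                                 m = 2, degree_seq = NULL, seed) {
  model <- match.arg(model)
  if (missing(seed)) abort("an RNG seed is required")
  if (n_nodes < 10) abort("n_nodes must be >= 10")
  g <- with_seed(seed, {
    if (model == "preferential_attachment") {
      igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    } else {
      if (is.null(degree_seq)) abort("configuration model needs degree_seq")
      if (length(degree_seq) != n_nodes) {
        abort("degree_seq length must equal n_nodes")
      }
      tryCatch(
        igraph::sample_degseq(degree_seq, method = "vl"),
        error = function(e) {
          abort(sprintf("infeasible degree sequence: %s", conditionMessage(e)))
        }
      )
    }
  })
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  igraph::V(g)$name <- synthetic_symbols(igraph::vcount(g))
  new_interactome(g, name = sprintf("synthetic-%s", model),
                  metadata = list(source = "synthetic", model = model,
                                  seed = seed,
                                  self_loops_dropped = 0L,
                                  duplicates_dropped = 0L))
}

#' Plant a densely interconnected candidate module in an interactome
#'
#' Picks `module_size` nodes, adds internal edges among them until their
#' internal density reaches `internal_p`, and assembles a candidate list of
#' the module plus `n_noise` random background nodes plus `n_unmapped`
#' fabricated symbols absent from the interactome (reserved prefix
#' `SYNUN`, so coverage reports are testable). Noise candidates are split
#' between proteomics and text-mining provenance, text-mining records
#' carrying z-scores that survive the default 0.1 filter.
#'
#' @param net An `interactome` (will be augmented with the planted edges).
#' @param module_size Number of module nodes.
#' @param internal_p Target internal edge density of the module, in (0, 1].
#' @param n_noise Number of background candidate nodes.
#' @param n_unmapped Number of fabricated unmapped candidate symbols.
#' @param seed Integer RNG seed.
#' @return A list with `net` (augmented interactome), `candidates`
#'   (record tibble) and `truth` (planted ground truth, JSON-serializable).
#' @export
plant_candidate_module <- function(net, module_size = 20, internal_p = 0.5,
                                   n_noise = 50, n_unmapped = 5, seed) {
  if (missing(seed)) abort("an RNG seed is required")
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  if (module_size > length(nodes)) abort("module_size exceeds network size")
  if (!(internal_p > 0 && internal_p <= 1)) {
    abort("internal_p must be in (0, 1]")
  }
  if (n_noise > length(nodes) - module_size) {
    abort("not enough background nodes for the requested noise candidates")
  }
  out <- with_seed(seed, {
    module <- sort(sample(nodes, module_size))
    # raise internal density to internal_p by adding missing module edges
    pairs <- utils::combn(module, 2)
    have <- igraph::get_edge_ids(g, as.vector(rbind(pairs[1, ],
                                                    pairs[2, ]))) > 0
    target <- ceiling(internal_p * ncol(pairs))
    need <- target - sum(have)
    if (need > 0) {
      missing_idx <- which(!have)
      add <- missing_idx[sample.int(length(missing_idx), need)]
      g <- igraph::add_edges(g, as.vector(rbind(pairs[1, add],
                                                pairs[2, add])))
    }
    noise <- sort(sample(setdiff(nodes, module), n_noise))
    unmapped <- if (n_unmapped > 0) sprintf("SYNUN%03d", seq_len(n_unmapped))
                else character(0)
    n_tm <- length(noise) %/% 2
    tm_noise <- noise[seq_len(n_tm)]
    prot_noise <- setdiff(noise, tm_noise)
    candidates <- dplyr::bind_rows(
      tibble(symbol = module, source = "proteomics", zscore = NA_real_),
      tibble(symbol = prot_noise, source = "proteomics", zscore = NA_real_),
      tibble(symbol = tm_noise, source = "text_mining",
             zscore = round(stats::runif(length(tm_noise), 0.1, 1), 3)),
      tibble(symbol = unmapped, source = "text_mining",
             zscore = round(stats::runif(length(unmapped), 0.1, 1), 3))
    )
    list(graph = g, module = module, candidates = candidates,
         unmapped = unmapped)
  })
  net2 <- new_interactome(out$graph, name = paste0(net$name, "+module"),
                          metadata = c(net$metadata,
                                       list(planted_module = TRUE)))
  truth <- list(
    planted_module = out$module,
    internal_p = internal_p,
    candidate_composition = list(n_signal = module_size,
                                 n_noise = n_noise,
                                 n_unmapped = n_unmapped),
    unmapped_symbols = out$unmapped,
    seed = seed
  )
  list(net = net2, candidates = out$candidates, truth = truth)
}

#' Generate a synthetic annotation database with planted enriched terms
#'
#' Background terms are uniform random draws from the interactome nodes;
#' each planted term is constructed to overlap a reference gene set (usually
#' the planted module) at a requested Jaccard index, giving enrichment
#' ground truth.
#'
#' @param net An `interactome`.
#' @param n_terms Number of background terms.
#' @param term_size_range Integer range of background term sizes.
#' @param planted List of planted-term specs: each a list with `genes`
#'   (character vector), `jaccard` (target Jaccard index with `genes`) and
#'   optional `name`.
#' @param seed Integer RNG seed.
#' @return A list with `gene_sets` (a `gene_set_collection`; planted terms
#'   first, ids `PLANTED1 ...`) and `truth` (per planted term: realized
#'   overlap and size).
#' @export
generate_annotation_db <- function(net, n_terms = 200,
                                   term_size_range = c(10, 50),
                                   planted = list(), seed) {
  if (missing(seed)) abort("an RNG seed is required")
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  if (max(term_size_range) > length(nodes)) {
    abort("term sizes exceed the number of network nodes")
  }
  res <- with_seed(seed, {
    planted_rows <- purrr::imap(planted, function(spec, i) {
      ref <- unique(toupper(spec$genes))
      j <- spec$jaccard
      s <- length(ref)
      # choose term size = reference size; jaccard j = o / (2s - o)
      o <- round(j * 2 * s / (1 + j))
      if (o < 1 || o > s) abort("requested planted overlap is infeasible")
      extra_pool <- setdiff(nodes, ref)
      n_extra <- s - o
      if (n_extra > length(extra_pool)) {
        abort("requested planted overlap is infeasible")
      }
      members <- sort(c(sample(ref, o),
                        if (n_extra > 0) sample(extra_pool, n_extra)))
      list(term_id = sprintf("PLANTED%d", i),
           term_name = spec$name %||% sprintf("planted term %d", i),
           genes = members, overlap = o, size = s)
    })
    bg_rows <- if (n_terms > 0) {
      sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                      n_terms, replace = TRUE)
      purrr::imap(sizes, function(sz, i) {
        list(term_id = sprintf("BG%04d", i),
             term_name = sprintf("background term %d", i),
             genes = sort(sample(nodes, sz)))
      })
    } else list()
    c(planted_rows, bg_rows)
  })
  if (length(res) == 0) {
    gs <- new_gene_set_collection(
      tibble(term_id = character(0), term_name = character(0),
             genes = list()), "synthetic")
    return(list(gene_sets = gs, truth = list(planted_terms = list(),
                                             seed = seed)))
  }
  gs <- new_gene_set_collection(
    tibble(term_id = vapply(res, `[[`, "", "term_id"),
           term_name = vapply(res, `[[`, "", "term_name"),
           genes = lapply(res, `[[`, "genes")),
    "synthetic"
  )
  planted_truth <- purrr::keep(res, ~ startsWith(.x$term_id, "PLANTED"))
  list(
    gene_sets = gs,
    truth = list(
      planted_terms = purrr::map(planted_truth, function(r) {
        list(term_id = r$term_id, overlap = r$overlap, size = r$size)
      }),
      n_background_terms = n_terms,
      seed = seed
    )
  )
}

#' Write a complete synthetic analysis bundle to disk
#'
#' Generates a scale-free interactome, plants a candidate module and an
#' enriched annotation term, and writes the exact file formats the pipeline
#' consumes: `interactome.tsv`, `candidates.tsv`, `annotations.gmt` and
#' `truth.json`. The default scale (500 nodes, 20-node module at density
#' 0.5, 50 noise candidates, 5 unmapped symbols, 200 background terms) keeps
#' a full pipeline run in the seconds range.
#'
#' @param dir Output directory (created if needed).
#' @param n_nodes,m Interactome scale, see [generate_interactome()].
#' @param module_size,internal_p,n_noise,n_unmapped Module planting, see
#'   [plant_candidate_module()].
#' @param n_terms,term_size_range,planted_jaccard Annotation generation, see
#'   [generate_annotation_db()].
#' @param seed Integer RNG seed driving all three generators.
#' @return Invisibly, a list with the four file `paths` and the combined
#'   `truth`.
#' @export
synth_bundle <- function(dir, n_nodes = 500, m = 2, module_size = 20,
                         internal_p = 0.5, n_noise = 50, n_unmapped = 5,
                         n_terms = 200, term_size_range = c(10, 50),
                         planted_jaccard = 0.8, seed) {
  if (missing(seed)) abort("an RNG seed is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_interactome(n_nodes, "preferential_attachment", m = m,
                              seed = seed)
  pl <- plant_candidate_module(net, module_size = module_size,
                               internal_p = internal_p, n_noise = n_noise,
                               n_unmapped = n_unmapped, seed = seed + 1)
  ann <- generate_annotation_db(pl$net, n_terms = n_terms,
                                term_size_range = term_size_range,
                                planted = list(list(
                                  genes = pl$truth$planted_module,
                                  jaccard = planted_jaccard,
                                  name = "planted disease module term")),
                                seed = seed + 2)
  paths <- list(
    interactome = file.path(dir, "interactome.tsv"),
    candidates = file.path(dir, "candidates.tsv"),
    gene_sets = file.path(dir, "annotations.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_network(pl$net, paths$interactome, format = "tsv")
  readr::write_tsv(pl$candidates, paths$candidates, progress = FALSE)
  write_gmt(ann$gene_sets, paths$gene_sets)
  truth <- c(pl$truth, ann$truth["planted_terms"],
             list(generator = list(n_nodes = n_nodes, m = m,
                                   n_terms = n_terms,
                                   term_size_range = term_size_range,
                                   planted_jaccard = planted_jaccard)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Read the ground-truth record written by [synth_bundle()]
#' @param path Path to `truth.json`.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
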