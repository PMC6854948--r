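# End-to-end orchestration: candidates -> disease network -> permutation
# test -> hub backbone -> per-category enrichment, with a run manifest so
# every reported count can be recomputed from the written files.

#' Assemble and validate a pipeline configuration
#'
#' @param interactome Path to the interactome edge list.
#' @param candidates Path to the candidate TSV (`symbol`, `source`,
#'   `zscore`).
#' @param gene_sets Named character vector or list of GMT paths, one per
#'   category (names become category labels).
#' @param out_dir Output directory for run artifacts.
#' @param seed Integer seed; the single source of randomness for the run.
#' @param symbol_map Optional path to a raw-to-canonical symbol map TSV.
#' @param background Optional path to a background gene list (one symbol per
#'   line). Default: genes present in both the annotation collections and
#'   the interactome, united with the query.
#' @param interactome_format `"tsv"`, `"sif"` or `"graphml"`.
#' @param zscore_threshold Text-mining relevance cut-off (default 0.1).
#' @param n_perm,statistic,degree_matched,bins Permutation-test settings,
#'   see [permutation_test()].
#' @param fraction,edge_agg Backbone settings, see [extract_backbone()].
#' @param mode,david_compat,p_cutoff,fdr_cutoff,filter Enrichment settings,
#'   see [enrich_category()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(interactome, candidates, gene_sets, out_dir,
                            seed, symbol_map = NULL, background = NULL,
                            interactome_format = c("tsv", "sif", "graphml"),
                            zscore_threshold = 0.1,
                            n_perm = 1000,
                            statistic = c("edge_count", "lcc_size"),
                            degree_matched = FALSE, bins = 10,
                            fraction = 0.10, edge_agg = c("max", "sum"),
                            mode = c("ease", "fisher"),
                            david_compat = FALSE,
                            p_cutoff = 0.05, fdr_cutoff = 10,
                            filter = FALSE) {
  cfg <- list(
    interactome = interactome, candidates = candidates,
    gene_sets = as.list(gene_sets), out_dir = out_dir, seed = seed,
    symbol_map = symbol_map, background = background,
    interactome_format = match.arg(interactome_format),
    zscore_threshold = zscore_threshold, n_perm = n_perm,
    statistic = match.arg(statistic),
    degree_matched = degree_matched, bins = bins,
    fraction = fraction, edge_agg = match.arg(edge_agg),
    mode = match.arg(mode), david_compat = david_compat,
    p_cutoff = p_cutoff, fdr_cutoff = fdr_cutoff, filter = filter
  )
  validate_pipeline_config(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to the YAML file; keys as in [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_pipeline_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "stonenet_validation_error")
  for (f in c("interactome", "candidates")) {
    if (!file.exists(cfg[[f]])) fail(sprintf("%s file not found: %s",
                                             f, cfg[[f]]))
  }
  if (length(cfg$gene_sets) == 0) fail("no gene-set files configured")
  if (is.null(names(cfg$gene_sets)) || any(!nzchar(names(cfg$gene_sets)))) {
    fail("gene_sets must be named by category")
  }
  for (p in cfg$gene_sets) {
    if (!file.exists(p)) fail(sprintf("gene-set file not found: %s", p))
  }
  for (f in c("symbol_map", "background")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      fail(sprintf("%s file not found: %s", f, cfg[[f]]))
    }
  }
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) fail("a seed is required")
  if (!(cfg$fraction > 0 && cfg$fraction <= 1)) {
    fail("fraction must be in (0, 1]")
  }
  if (cfg$n_perm < 1) fail("n_perm must be >= 1")
  if (cfg$p_cutoff <= 0 || cfg$fdr_cutoff <= 0) {
    fail("thresholds must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

stage_banner <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "stonenet_validation_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "stonenet_stage_error")
  })
}

#' Run the full disease-network analysis pipeline
#'
#' Executes, in order: candidate loading and z-score filtering (with
#' optional symbol normalization), interactome mapping with a coverage
#' report, disease-network construction, the permutation connectivity test,
#' centrality ranking and backbone extraction, and per-category
#' over-representation analysis; writes all artifacts plus a `manifest.json`
#' echoing the configuration and every stage's counts. Validation errors are
#' raised before any computation; stage failures abort with a stage-named
#' error.
#'
#' @param config A `pipeline_config` (or path to a YAML config file).
#' @return Invisibly, a list with the run directory and all stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  net <- run_stage("load_interactome", {
    n <- if (cfg$interactome_format == "graphml") read_graphml(cfg$interactome)
         else read_edge_list(cfg$interactome,
                             format = cfg$interactome_format)
    stage_banner("load_interactome", "%d nodes, %d edges",
                 igraph::vcount(n$graph), igraph::ecount(n$graph))
    n
  })

  cand <- run_stage("assemble_candidates", {
    recs <- read_candidates(cfg$candidates)
    recs <- filter_by_zscore(recs, threshold = cfg$zscore_threshold)
    if (!is.null(cfg$symbol_map)) {
      map <- read_symbol_map(cfg$symbol_map)
      up <- toupper(recs$symbol)
      canon <- unname(map[up])
      canon[is.na(canon) & up %in% unname(map)] <-
        up[is.na(canon) & up %in% unname(map)]
      # records with no mapping keep their raw (uppercased) symbol and are
      # reported as unmapped at the interactome-coverage stage
      recs$symbol <- canon %|NA|% up
    }
    cs <- merge_candidates(recs)
    stage_banner("assemble_candidates", "%d records -> %d unique symbols",
                 nrow(cs$records), length(cs$symbols))
    cs
  })

  mapping <- run_stage("map_candidates", {
    mp <- map_to_interactome(cand, net)
    cov <- tibble(symbol = c(mp$mapped_symbols, mp$unmapped),
                  mapped = c(rep(TRUE, length(mp$mapped_symbols)),
                             rep(FALSE, length(mp$unmapped))))
    readr::write_tsv(cov, file.path(cfg$out_dir, "coverage.tsv"),
                     progress = FALSE)
    stage_banner("map_candidates", "%d/%d mapped (coverage %.3f)",
                 length(mp$mapped_symbols), length(cand$symbols),
                 mp$coverage)
    mp
  })

  dnet <- run_stage("disease_network", {
    d <- build_disease_network(net, mapping$mapped_symbols)
    write_network(d, file.path(cfg$out_dir, "disease_network.tsv"), "tsv")
    write_network(d, file.path(cfg$out_dir, "disease_network.sif"), "sif")
    stage_banner("disease_network",
                 "%d nodes, %d edges (%d isolates dropped)",
                 igraph::vcount(d$graph), igraph::ecount(d$graph),
                 length(d$dropped_isolates))
    d
  })

  perm <- run_stage("permutation_test", {
    p <- permutation_test(net, node_names(dnet), n_perm = cfg$n_perm,
                          statistic = cfg$statistic,
                          degree_matched = cfg$degree_matched,
                          bins = cfg$bins, seed = cfg$seed)
    jsonlite::write_json(glance(p), file.path(cfg$out_dir,
                                              "permutation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    readr::write_tsv(tidy(p), file.path(cfg$out_dir, "null_values.tsv"),
                     progress = FALSE)
    stage_banner("permutation_test", "observed %s = %g, p = %.4g",
                 cfg$statistic, p$observed, p$p_value)
    p
  })

  bb <- run_stage("backbone", {
    b <- extract_backbone(dnet, fraction = cfg$fraction,
                          edge_agg = cfg$edge_agg)
    ct <- tidy(b)
    ct_out <- ct
    readr::write_tsv(ct_out, file.path(cfg$out_dir, "centrality.tsv"),
                     progress = FALSE)
    write_network(b, file.path(cfg$out_dir, "backbone.sif"), "sif")
    write_network(b, file.path(cfg$out_dir, "backbone.graphml"), "graphml",
                  node_attrs = ct[c("symbol", "degree", "betweenness",
                                    "edge_btw_score", "composite_rank",
                                    "is_hub")])
    stage_banner("backbone", "%d hubs, %d backbone edges",
                 length(b$hub_symbols), igraph::ecount(b$graph))
    b
  })

  enr <- run_stage("enrichment", {
    collections <- purrr::imap(cfg$gene_sets,
                               function(p, cat) read_gmt(p, category = cat))
    ann_genes <- unique(toupper(unlist(purrr::map(collections,
                                                  ~ unlist(.x$genes)))))
    background <- if (!is.null(cfg$background)) {
      toupper(trimws(readLines(cfg$background, warn = FALSE)))
    } else {
      union(intersect(ann_genes, node_names(net)), bb$hub_symbols)
    }
    background <- unique(background[nzchar(background)])
    res <- enrich_collections(bb$hub_symbols, collections, background,
                              mode = cfg$mode,
                              david_compat = cfg$david_compat,
                              p_cutoff = cfg$p_cutoff,
                              fdr_cutoff = cfg$fdr_cutoff,
                              filter = cfg$filter)
    for (cat in names(res)) {
      write_enrichment_tsv(res[[cat]],
                           file.path(cfg$out_dir,
                                     sprintf("enrichment_%s.tsv", cat)))
    }
    n_sig <- purrr::map_int(res, function(x) {
      sum(x$p_value < cfg$p_cutoff & x$fdr_percent < cfg$fdr_cutoff)
    })
    stage_banner("enrichment", "significant terms: %s",
                 paste(sprintf("%s=%d", names(n_sig), n_sig),
                       collapse = ", "))
    list(results = res, n_significant = n_sig,
         n_background = length(background))
  })

  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("stonenet")),
    counts = list(
      candidate_records = nrow(cand$records),
      candidate_symbols = length(cand$symbols),
      mapped_candidates = length(mapping$mapped_symbols),
      coverage = mapping$coverage,
      disease_network_nodes = igraph::vcount(dnet$graph),
      disease_network_edges = igraph::ecount(dnet$graph),
      isolates_dropped = length(dnet$dropped_isolates),
      permutation_observed = perm$observed,
      permutation_p = perm$p_value,
      n_hubs = length(bb$hub_symbols),
      backbone_edges = igraph::ecount(bb$graph),
      significant_terms = as.list(enr$n_significant),
      enrichment_background = enr$n_background
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, net = net, candidates = cand,
                 mapping = mapping, disease_network = dnet,
                 permutation = perm, backbone = bb,
                 enrichment = enr$results, manifest = manifest))
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Write a human-readable run summary
#'
#' Re-reads a completed run's manifest and writes `report.txt` tracing the
#' candidates -> disease network -> backbone -> enrichment progression.
#'
#' @param run_dir A pipeline output directory.
#' @return The report lines, invisibly; the report is written to
#'   `report.txt` in `run_dir`.
#' @export
write_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  required <- c("manifest.json", "coverage.tsv", "disease_network.tsv",
                "permutation.json", "centrality.tsv", "backbone.sif")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing) > 0) {
    abort(sprintf("incomplete run; missing artifacts: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cnt <- m$counts
  sig <- cnt$significant_terms
  lines <- c(
    "== disease-network analysis run summary ==",
    sprintf("seed: %s", m$seed),
    sprintf("%d candidate records -> %d unique candidate symbols",
            cnt$candidate_records, cnt$candidate_symbols),
    sprintf("%d candidates mapped to the interactome (coverage %.3f)",
            cnt$mapped_candidates, cnt$coverage),
    sprintf("disease network: %d nodes, %d edges (%d isolates dropped)",
            cnt$disease_network_nodes, cnt$disease_network_edges,
            cnt$isolates_dropped),
    sprintf("permutation test: observed = %g, p = %.4g",
            cnt$permutation_observed, cnt$permutation_p),
    sprintf("%d backbone genes (%d backbone edges)",
            cnt$n_hubs, cnt$backbone_edges),
    sprintf("significant terms (p < %g and FDR%% < %g): %s",
            m$config$p_cutoff, m$config$fdr_cutoff,
            if (length(sig)) paste(sprintf("%s = %d", names(sig),
                                           unlist(sig)),
                                   collapse = ", ")
            else "0")
  )
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
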