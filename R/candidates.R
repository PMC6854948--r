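# Candidate assembly: pool disease-protein records from provenance-tagged
# sources (proteomics, text mining), apply the text-mining relevance filter,
# deduplicate, and map the result onto the interactome.

#' Read a candidate-protein table
#'
#' TSV with header columns `symbol`, `source` and `zscore`. `source` is one of
#' `proteomics`, `text_mining`, `other`; `zscore` is the text-mining relevance
#' score and must be present exactly for `text_mining` records (blank
#' otherwise).
#'
#' @param path Path to the TSV file.
#' @return A tibble of candidate records with uppercase symbols.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    symbol = readr::col_character(),
    source = readr::col_character(),
    zscore = readr::col_double()
  ), progress = FALSE)
  validate_candidate_records(df)
}

validate_candidate_records <- function(df) {
  df <- as_tibble(df)
  if (!all(c("symbol", "source") %in% names(df))) {
    abort("candidate table needs columns: symbol, source")
  }
  if (!"zscore" %in% names(df)) df$zscore <- NA_real_
  df$symbol <- toupper(trimws(df$symbol))
  if (any(!nzchar(df$symbol))) abort("empty candidate symbol")
  bad <- !df$source %in% c("proteomics", "text_mining", "other")
  if (any(bad)) {
    abort(sprintf("unknown candidate source: %s",
                  paste(unique(df$source[bad]), collapse = ", ")))
  }
  if (any(df$source != "text_mining" & !is.na(df$zscore))) {
    abort("zscore is only meaningful for text_mining records")
  }
  df[c("symbol", "source", "zscore")]
}

#' Filter text-mining candidates by relevance z-score
#'
#' Text-mining records are retained when `zscore >= threshold` (the boundary
#' is inclusive); records from other sources pass unchanged. Input order is
#' preserved. The default threshold of 0.1 is the conventional PolySearch
#' relevance cut-off for disease-gene retrieval.
#'
#' @param records Candidate record tibble (see [read_candidates()]).
#' @param threshold Finite z-score cut-off, default 0.1.
#' @return The filtered record tibble.
#' @export
filter_by_zscore <- function(records, threshold = 0.1) {
  records <- validate_candidate_records(records)
  if (!is.finite(threshold)) abort("threshold must be finite")
  tm <- records$source == "text_mining"
  if (any(tm & is.na(records$zscore))) {
    abort("text_mining record lacking a zscore")
  }
  records[!tm | records$zscore >= threshold, ]
}

#' Merge candidate lists into a deduplicated candidate set
#'
#' Takes any number of candidate record tibbles (or bare character vectors,
#' which are tagged `source = "other"`), pools them, and deduplicates by
#' symbol while keeping every provenance tag. This mirrors pooling a
#' proteomics hit list with a text-mining list and counting the union after
#' duplicate removal.
#'
#' @param ... Candidate record tibbles and/or character vectors of symbols.
#' @return A `candidate_set`: list with `records` (all rows), `symbols`
#'   (sorted unique), `per_source` (named counts of records by source).
#' @export
merge_candidates <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 0) abort("no candidate lists supplied")
  recs <- purrr::map(inputs, function(x) {
    if (is.character(x)) {
      x <- tibble(symbol = x, source = "other", zscore = NA_real_)
    }
    validate_candidate_records(x)
  })
  records <- dplyr::bind_rows(recs)
  symbols <- sort(unique(records$symbol))
  if (length(symbols) == 0) abort("empty candidate union")
  per_source <- table(records$source)
  structure(
    list(records = records,
         symbols = symbols,
         per_source = stats::setNames(as.integer(per_source),
                                      names(per_source))),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d unique symbols from %d records (%s)\n",
              length(x$symbols), nrow(x$records),
              paste(sprintf("%s: %d", names(x$per_source), x$per_source),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.candidate_set <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source)), collapse = ","),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$symbol)
}

#' @export
glance.candidate_set <- function(x, ...) {
  tibble(n_symbols = length(x$symbols),
         n_records = nrow(x$records),
         n_duplicate_records = nrow(x$records) - length(x$symbols))
}

#' Map a candidate set onto an interactome
#'
#' Intersects candidate symbols with the interactome node universe. Unmapped
#' candidates are reported, never silently dropped; an empty intersection is
#' an error because no downstream stage can proceed.
#'
#' @param cands A `candidate_set` (from [merge_candidates()]) or a character
#'   vector of symbols.
#' @param net An `interactome`.
#' @return A list with `mapped_symbols` (sorted), `unmapped` (sorted) and
#'   `coverage` (fraction of candidate symbols present in the interactome).
#' @export
map_to_interactome <- function(cands, net) {
  symbols <- if (inherits(cands, "candidate_set")) cands$symbols
             else sort(unique(toupper(trimws(cands))))
  nodes <- node_names(net)
  mapped <- sort(intersect(symbols, nodes))
  if (length(mapped) == 0) {
    abort("no candidate maps to the interactome; pipeline cannot proceed")
  }
  list(
    mapped_symbols = mapped,
    unmapped = sort(setdiff(symbols, nodes)),
    coverage = length(mapped) / length(symbols)
  )
}
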