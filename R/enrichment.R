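# Over-representation analysis (ORA) of a query gene list against gene-set
# categories, with DAVID-compatible column semantics: Count, %, P value
# (hypergeometric tail or EASE), Benjamini, FDR (percent scale), Genes.

#' 2x2 overlap margins for a query/term pair
#'
#' @param query Character vector of query genes (must be a subset of
#'   `background`).
#' @param term_genes Character vector of term member genes; only members
#'   present in the background count toward K.
#' @param background Character vector: the gene universe.
#' @return A list with `k` (query-in-term), `K` (term-in-background),
#'   `n` (query size), `N` (background size).
#' @export
overlap_table <- function(query, term_genes, background) {
  background <- unique(toupper(background))
  if (length(background) == 0) abort("empty background")
  query <- unique(toupper(query))
  if (!all(query %in% background)) {
    abort("query must be a subset of the background universe")
  }
  term_bg <- intersect(unique(toupper(term_genes)), background)
  list(k = length(intersect(query, term_bg)),
       K = length(term_bg),
       n = length(query),
       N = length(background))
}

#' Hypergeometric / EASE enrichment p-value
#'
#' `fisher` is the one-sided hypergeometric tail P\[X >= k\] with X ~
#' Hypergeometric(N, K, n). `ease` is DAVID's conservative variant: the same
#' tail computed after discounting one overlapping gene, P\[X >= k - 1\]
#' (so `ease >= fisher` for every table). `k = 0` gives p = 1 in both modes.
#'
#' @param k Query genes in the term.
#' @param K Term genes in the background.
#' @param n Query size.
#' @param N Background size.
#' @param mode `"fisher"` or `"ease"`.
#' @return The p-value, in (0, 1].
#' @export
enrichment_pvalue <- function(k, K, n, N, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N) {
    abort("inconsistent contingency margins")
  }
  kk <- if (mode == "ease") max(k - 1, 0) else k
  if (kk == 0) return(1)
  # P[X >= kk] = upper tail at kk - 1
  stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment (standard or DAVID-compatible)
#'
#' Standard mode is the usual BH step-up over `m` tests (monotone in rank,
#' capped at 1), delegated to [stats::p.adjust()]. DAVID-compatible mode
#' reproduces the raw `p * m / rank` column DAVID prints, i.e. without the
#' step-up minimum, so adjacent rows need not be monotone.
#'
#' @param pvalues Numeric vector in (0, 1].
#' @param m Number of tests (>= `length(pvalues)`); defaults to the length.
#' @param david_compat Use the non-monotone `p * m / rank` form?
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues, m = NULL, david_compat = FALSE) {
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    abort("p-values must lie in (0, 1]")
  }
  m <- m %||% length(pvalues)
  if (m < length(pvalues)) abort("m must be >= length(pvalues)")
  if (!david_compat) {
    return(stats::p.adjust(pvalues, method = "BH", n = m))
  }
  ord <- order(pvalues)
  r <- integer(length(pvalues))
  r[ord] <- seq_along(pvalues)
  pmin(pvalues * m / r, 1)
}

#' DAVID-style percent-scale FDR
#'
#' `100 * (1 - (1 - p)^m)`: the probability, on the percent scale, of at
#' least one false positive among `m` independent tests at level `p`
#' (first-order `100 * m * p` for small p). This is the family consistent
#' with DAVID's per-category constant p-to-FDR ratio; it is an approximation
#' and is flagged as such in reports. `m` may be non-integer.
#'
#' @param p P-value(s) in (0, 1].
#' @param m Effective number of tests, >= 1.
#' @return FDR on the percent scale (0-100].
#' @export
fdr_percent <- function(p, m) {
  if (any(p <= 0 | p > 1)) abort("p must lie in (0, 1]")
  if (any(m < 1)) abort("m must be >= 1")
  100 * -expm1(m * log1p(-p))
}

#' Over-representation analysis of one gene-set category
#'
#' Tests the query list against every term of a category. One row is
#' reported per term with at least one query gene; the multiple-testing
#' denominator `m` nevertheless counts every term with at least one
#' background gene, because corrections reflect tests performed rather than
#' rows displayed. Rows are sorted ascending by p, with reported gene lists
#' sorted so output is byte-reproducible.
#'
#' @param query Character vector of query genes (the backbone gene list).
#' @param gene_sets A `gene_set_collection` (see [read_gmt()]).
#' @param background Gene universe; must contain the query. Typically the
#'   genes present in both the annotation collection and the interactome.
#' @param mode `"ease"` (DAVID parity, default) or `"fisher"`.
#' @param david_compat Benjamini column without step-up, see [bh_adjust()].
#' @param p_cutoff,fdr_cutoff Significance thresholds applied when
#'   `filter = TRUE`: p < `p_cutoff` and FDR percent < `fdr_cutoff`
#'   (defaults 0.05 and 10).
#' @param filter Keep only rows passing both thresholds?
#' @return An `enrichment_result` tibble with columns `term_id`,
#'   `term_name`, `count`, `percent`, `p_value`, `benjamini`, `fdr_percent`,
#'   `genes` (list-column, sorted) and attributes `category`, `m`,
#'   `n_query`, `n_background`, `mode`.
#' @export
enrich_category <- function(query, gene_sets, background,
                            mode = c("ease", "fisher"),
                            david_compat = FALSE,
                            p_cutoff = 0.05, fdr_cutoff = 10,
                            filter = FALSE) {
  mode <- match.arg(mode)
  query <- unique(toupper(query))
  if (length(query) == 0) abort("empty query gene list")
  background <- unique(toupper(background))
  if (length(background) < length(query)) {
    abort("background smaller than query")
  }
  if (!all(query %in% background)) {
    abort("query must be a subset of the background universe")
  }
  category <- attr(gene_sets, "category") %||% NA_character_

  tabs <- purrr::map(gene_sets$genes, overlap_table,
                     query = query, background = background)
  K <- vapply(tabs, `[[`, 0, "K")
  k <- vapply(tabs, `[[`, 0, "k")
  tested <- K >= 1
  m <- sum(tested)

  res <- tibble(
    term_id = gene_sets$term_id[tested],
    term_name = gene_sets$term_name[tested],
    count = as.integer(k[tested]),
    K = as.integer(K[tested]),
    genes = purrr::map(which(tested), function(i) {
      sort(intersect(query, toupper(gene_sets$genes[[i]])))
    })
  )
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    enrichment_pvalue(res$count[i], res$K[i], length(query),
                      length(background), mode = mode)
  }, numeric(1))
  res$benjamini <- if (m > 0) {
    bh_adjust(res$p_value, m = m, david_compat = david_compat)
  } else numeric(0)
  res$fdr_percent <- if (m > 0) fdr_percent(res$p_value, m) else numeric(0)
  res$percent <- 100 * res$count / length(query)

  res <- res |>
    dplyr::filter(.data$count >= 1) |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "count", "percent", "p_value",
                  "benjamini", "fdr_percent", "genes")
  if (filter) {
    res <- dplyr::filter(res, .data$p_value < p_cutoff,
                         .data$fdr_percent < fdr_cutoff)
  }
  structure(res,
            category = category, m = m,
            n_query = length(query), n_background = length(background),
            mode = mode,
            class = c("enrichment_result", class(tibble())))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(category = attr(x, "category"),
         n_terms_reported = nrow(x),
         m_tests = attr(x, "m"),
         n_query = attr(x, "n_query"),
         n_background = attr(x, "n_background"),
         mode = attr(x, "mode"))
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  out$genes <- vapply(out$genes, paste, character(1), collapse = ", ")
  out
}

#' @rdname enrich_category
#' @param object An `enrichment_result`.
#' @param n_terms Show at most this many top terms.
#' @param ... Ignored.
#' @export
autoplot.enrichment_result <- function(object, n_terms = 15, ...) {
  df <- utils::head(as_tibble(object), n_terms)
  df$term <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$term,
                                   size = .data$count,
                                   colour = .data$percent)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL,
                  size = "count", colour = "% of query",
                  title = attr(object, "category")) +
    ggplot2::theme_minimal()
}

#' Run ORA across several categories
#'
#' @param query Query gene list.
#' @param collections Named list of `gene_set_collection`s (e.g. BP, CC, MF,
#'   KEGG); corrections are computed per category.
#' @param background Gene universe shared across categories.
#' @inheritParams enrich_category
#' @return A named list of `enrichment_result`s.
#' @export
enrich_collections <- function(query, collections, background,
                               mode = c("ease", "fisher"),
                               david_compat = FALSE,
                               p_cutoff = 0.05, fdr_cutoff = 10,
                               filter = FALSE) {
  mode <- match.arg(mode)
  purrr::map(collections, enrich_category,
             query = query, background = background, mode = mode,
             david_compat = david_compat, p_cutoff = p_cutoff,
             fdr_cutoff = fdr_cutoff, filter = filter)
}

#' Write an enrichment result as a DAVID-style TSV
#'
#' Columns: Term, Count, %, PValue, Benjamini, FDR, Genes. The FDR column is
#' the approximate percent-scale estimate of [fdr_percent()].
#'
#' @param x An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path) {
  out <- tibble(
    Term = paste0(x$term_id, "~", x$term_name),
    Count = x$count,
    `%` = x$percent,
    PValue = x$p_value,
    Benjamini = x$benjamini,
    FDR = x$fdr_percent,
    Genes = vapply(x$genes, paste, character(1), collapse = ", ")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
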