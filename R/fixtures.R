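# Packaged reference fixture: the published GO/KEGG over-representation
# table for the 31-protein kidney-stone backbone network (categories BP, CC,
# MF, KEGG with Count, %, P value, Benjamini, FDR-percent and gene lists).
# The fixture is the transcription of the published table; its P/Benjamini/
# FDR values were produced against DAVID's proprietary background and are
# carried for reference, not re-derived here.

fixture_path <- function(file) {
  system.file("extdata", file, package = "stonenet", mustWork = TRUE)
}

#' Published backbone ORA reference table
#'
#' The full published over-representation table for the 31-gene kidney-stone
#' backbone: 36 terms across BP, CC, MF and KEGG with the printed Count, %,
#' P value, Benjamini, FDR (percent) and per-term gene lists.
#'
#' @return A tibble with columns `category`, `term_id`, `term_name`,
#'   `count`, `percent`, `p_value`, `benjamini`, `fdr_percent` and the
#'   list-column `genes`.
#' @export
kidney_stone_go_fixture <- function() {
  x <- readr::read_tsv(fixture_path("kidney_stone_go.tsv"),
                       col_types = "ccciddddc", progress = FALSE)
  x$genes <- strsplit(x$genes, ",", fixed = TRUE)
  x
}

#' Gene-set collections of the backbone ORA reference table
#'
#' @return A named list of `gene_set_collection`s (BP, CC, MF, KEGG), each
#'   read from the packaged GMT fixture files.
#' @export
kidney_stone_gene_sets <- function() {
  cats <- c("BP", "CC", "MF", "KEGG")
  stats::setNames(lapply(cats, function(cat) {
    read_gmt(fixture_path(sprintf("kidney_stone_%s.gmt", tolower(cat))),
             category = cat)
  }), cats)
}

#' The 31 published backbone hub genes
#'
#' The union of all gene lists in the reference ORA table: the 31 hub
#' proteins of the published backbone network.
#'
#' @return Sorted character vector of 31 gene symbols.
#' @export
kidney_stone_backbone_genes <- function() {
  sort(unique(unlist(kidney_stone_go_fixture()$genes)))
}
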