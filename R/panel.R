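#' The 14-gene DDR-collagen-MMP panel
#'
#' The panel spans the collagen-sensing circuit studied across the colorectal
#' adenoma-carcinoma sequence: the two discoidin domain receptors, seven
#' fibrillar-collagen/matrix genes that act as DDR ligands or structural
#' components, and five matrix metalloproteinases that execute remodeling.
#'
#' @return Character vector of the 14 gene symbols, in canonical panel order.
#' @export
#' @examples
#' panel_genes()
panel_genes <- function() {
  c(
    "DDR1", "DDR2",
    "COL1A1", "COL1A2", "COL3A1", "COL5A1", "COL5A2", "COL11A1", "FN1",
    "MMP1", "MMP2", "MMP7", "MMP9", "MMP11"
  )
}

#' Functional categories of the panel genes
#'
#' @return A tibble with columns `gene` and `category`
#'   (`receptor`, `collagen`, `mmp`). FN1 is grouped with the collagens as a
#'   structural matrix component.
#' @export
#' @examples
#' panel_categories()
panel_categories <- function() {
  tibble::tibble(
    gene = panel_genes(),
    category = c(
      "receptor", "receptor",
      rep("collagen", 7L),
      rep("mmp", 5L)
    )
  )
}

#' Target set of a hub receptor
#'
#' Each receptor is summarised against the 12 non-receptor panel genes; the
#' DDR1-DDR2 pair is excluded from hub summaries (though it is retained in the
#' full pairwise correlation tables).
#'
#' @param hub Hub gene symbol, typically `"DDR2"` or `"DDR1"`.
#' @param genes Panel gene set (default [panel_genes()]).
#' @return Character vector of target genes: all panel genes that are neither
#'   the hub nor another receptor.
#' @export
hub_targets <- function(hub, genes = panel_genes()) {
  stopifnot(hub %in% genes)
  receptors <- c("DDR1", "DDR2")
  setdiff(genes, union(hub, intersect(receptors, genes)))
}

#' Canonical disease-stage ordering
#'
#' @return `c("normal", "adenoma", "carcinoma")`.
#' @export
stage_levels <- function() c("normal", "adenoma", "carcinoma")
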