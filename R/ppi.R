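#' Read STRING-style flat files
#'
#' Both dialects are whitespace- or tab-delimited with a header line:
#' the detailed-links file carries `protein1`, `protein2` and per-channel
#' integer scores (0-1000); the alias file carries `protein_id`, `alias`,
#' `source` (leading `#` on the header is tolerated).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_string_links <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  tibble::as_tibble(tab)
}

#' @rdname read_string_links
#' @export
read_string_aliases <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  names(tab)[1:3] <- c("protein_id", "alias", "source")
  tibble::as_tibble(tab)
}

#' Map panel gene symbols to canonical protein identifiers
#'
#' @param aliases Alias tibble (`protein_id`, `alias`, `source`).
#' @param symbols Panel gene symbols to map.
#' @return List: `map` tibble (`gene`, `protein_id`) for mapped symbols and
#'   `unmapped` character vector. A symbol resolving to several distinct
#'   protein identifiers is an error listing the candidates.
#' @export
map_aliases <- function(aliases, symbols) {
  stopifnot(all(c("protein_id", "alias") %in% names(aliases)))
  aliases <- dplyr::distinct(aliases, .data$protein_id, .data$alias)
  hits <- aliases[aliases$alias %in% symbols, ]
  conflicts <- hits |>
    dplyr::group_by(.data$alias) |>
    dplyr::summarise(n_ids = dplyr::n_distinct(.data$protein_id),
                     ids = paste(unique(.data$protein_id), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_ids > 1L)
  if (nrow(conflicts) > 0L) {
    abort(paste0(
      "conflicting canonical ids: ",
      paste(paste0(conflicts$alias, " -> {", conflicts$ids, "}"),
            collapse = "; ")
    ))
  }
  map <- hits |>
    dplyr::distinct(.data$alias, .data$protein_id) |>
    dplyr::transmute(gene = .data$alias, protein_id = .data$protein_id)
  list(map = map, unmapped = setdiff(symbols, map$gene))
}

#' Filter interaction links to within-panel pairs and tabulate thresholds
#'
#' Retains rows where both partners map into the panel, collapses directed
#' duplicates to one record per unordered pair (keeping the maximum score
#' per channel, which for STRING's symmetric files is a no-op), and counts,
#' for each threshold, the pairs whose experimental-channel score meets it.
#'
#' @param links Links tibble with `protein1`, `protein2` and score columns
#'   (at least `experimental`; `database` and `combined_score` kept when
#'   present). Rows with malformed scores are skipped and counted.
#' @param id_map Tibble `gene`, `protein_id` from [map_aliases()].
#' @param thresholds Experimental-score thresholds; the conventional set is
#'   `c(1, 150, 400, 700, 900)` (a score of at least 1 meaning "> 0").
#' @return List: `edges` tibble (`gene_a` < `gene_b`, channel scores),
#'   `counts` tibble (`threshold`, `n_edges`), `n_skipped` malformed rows.
#' @export
filter_panel_edges <- function(links, id_map,
                               thresholds = c(1, 150, 400, 700, 900)) {
  stopifnot(all(c("protein1", "protein2", "experimental") %in% names(links)),
            all(c("gene", "protein_id") %in% names(id_map)))
  score_cols <- intersect(c("experimental", "database", "combined_score"),
                          names(links))
  scores_num <- lapply(links[score_cols], function(v) {
    suppressWarnings(as.numeric(v))
  })
  bad <- Reduce(`|`, lapply(scores_num, function(v) {
    is.na(v) | v < 0 | v > 1000
  }))
  n_skipped <- sum(bad)
  links <- links[!bad, , drop = FALSE]
  for (col in score_cols) links[[col]] <- as.numeric(links[[col]])

  lut <- setNames(id_map$gene, id_map$protein_id)
  ga <- unname(lut[links$protein1])
  gb <- unname(lut[links$protein2])
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  edges <- tibble::tibble(
    gene_a = pmin(ga[keep], gb[keep]),
    gene_b = pmax(ga[keep], gb[keep])
  )
  edges <- dplyr::bind_cols(edges, links[keep, score_cols, drop = FALSE])
  if (nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(score_cols), max),
                       .groups = "drop")
  }

  counts <- tibble::tibble(
    threshold = thresholds,
    n_edges = vapply(thresholds, function(t) {
      sum(edges$experimental >= t)
    }, numeric(1))
  )
  list(edges = edges, counts = counts, n_skipped = n_skipped)
}
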