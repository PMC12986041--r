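#' @importFrom rlang .data abort warn
#' @importFrom stats sd var cor pt pf ptukey qnorm runif rnorm model.matrix
#'   predict as.dist hclust setNames aggregate
#' @importFrom utils head modifyList
NULL

# Expression tables travel as tibbles: first column `gene_id`, one column per
# sample. These helpers convert to/from the numeric matrix used internally.

#' Convert an expression tibble to a gene-by-sample matrix
#'
#' @param expr Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @return Numeric matrix with genes as rownames, samples as colnames.
#' @export
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  genes <- as.character(expr[["gene_id"]])
  if (anyDuplicated(genes)) abort("duplicate gene_id values in expression table")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- genes
  m
}

#' Convert a gene-by-sample matrix to an expression tibble
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return Tibble with `gene_id` first.
#' @export
expr_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

validate_expression <- function(expr, annotation = NULL) {
  m <- expr_matrix(expr)
  if (anyNA(m)) abort("expression table contains missing values")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in expression table")
  if (!is.null(annotation)) {
    stopifnot(all(c("sample_id", "stage") %in% names(annotation)))
    if (!setequal(colnames(m), annotation$sample_id) ||
      anyDuplicated(annotation$sample_id)) {
      abort("annotation must contain exactly one row per expression sample")
    }
    bad <- setdiff(unique(annotation$stage), stage_levels())
    if (length(bad) > 0) {
      abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
    }
  }
  invisible(m)
}

# Deterministic per-module seed derivation from one global seed: a small
# polynomial hash of the module name folded into the 31-bit integer range.
derive_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(module)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) + 7919 * h) %% 2147483647)
}

#' Write / read the package's expression and annotation TSV formats
#'
#' Expression: first column `gene_id`, remaining columns sample ids, values
#' log2 expression. Annotation: columns `sample_id`, `stage`, `batch`.
#'
#' @param expr,annotation Tibbles in package format.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name coupling_io
NULL

#' @rdname coupling_io
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname coupling_io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname coupling_io
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(all(c("sample_id", "stage", "batch") %in% names(annotation)))
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname coupling_io
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    stage = readr::col_character(),
                    batch = readr::col_character()
                  ))
}
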