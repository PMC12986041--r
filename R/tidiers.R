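#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a batch-correction model
#'
#' One row per (gene, batch) with the raw and shrunk additive and
#' multiplicative batch-effect estimates.
#'
#' @param x A `batch_model` from [correct_batch_effects()].
#' @param ... Unused.
#' @export
tidy.batch_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batches, gene = x$genes) |>
    dplyr::relocate("gene") |>
    dplyr::mutate(
      gamma_hat = as.vector(x$additive_batch),
      delta_hat = as.vector(x$multiplicative_batch),
      gamma_star = as.vector(x$additive_batch_shrunk),
      delta_star = as.vector(x$multiplicative_batch_shrunk)
    )
}

#' @export
glance.batch_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_batches = length(x$batches),
    n_flagged = length(x$flagged_genes)
  )
}

#' Tidy differential-expression results
#'
#' @param x A `stage_de` from [differential_expression()].
#' @param type `"genes"` for the per-gene ANOVA table, `"pairwise"` for the
#'   Tukey stage-pair comparisons.
#' @param ... Unused.
#' @export
tidy.stage_de <- function(x, type = c("genes", "pairwise"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @export
glance.stage_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_significant = sum(x$genes$q_value < x$alpha),
    alpha = x$alpha
  )
}

#' Per-epoch training history of a classifier
#'
#' @param x A `coupling_classifier`.
#' @param ... Unused.
#' @export
tidy.coupling_classifier <- function(x, ...) x$history

#' @export
glance.coupling_classifier <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_val_accuracy = x$best_val_accuracy,
    final_learning_rate = x$history$learning_rate[nrow(x$history)],
    n_parameters = sum(vapply(x$params$layers, function(l) {
      length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
    }, numeric(1))) + length(x$params$out$W) + length(x$params$out$b)
  )
}

#' @export
tidy.classification_metrics <- function(x, ...) x$per_class

#' @export
glance.classification_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_f1 = mean(x$per_class$f1, na.rm = TRUE),
    macro_auc = mean(x$per_class$auc, na.rm = TRUE)
  )
}

#' @export
tidy.attribution_result <- function(x, ...) attribution_table(x)
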