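#' Plot coupling trajectories across stages
#'
#' @param trajectories Tibble from [coupling_trajectories()].
#' @param pairs Optional two-column data frame restricting which pairs to
#'   draw.
#' @param stages Ordered stages (must match the trajectory columns).
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, pairs = NULL,
                              stages = stage_levels()) {
  if (!is.null(pairs)) {
    trajectories <- dplyr::semi_join(trajectories, pairs,
                                     by = c("gene_a", "gene_b"))
  }
  long <- trajectories |>
    dplyr::mutate(pair = paste0(.data$gene_a, "-", .data$gene_b)) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("r2_", stages)),
                        names_to = "stage", values_to = "r2") |>
    dplyr::mutate(stage = factor(sub("^r2_", "", .data$stage),
                                 levels = stages))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$r2,
                                     group = .data$pair,
                                     colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(R^2), colour = "pair") +
    ggplot2::theme_minimal()
}

#' Heatmap of one stage's correlation matrix
#'
#' @param records Correlation table from [stage_correlation_table()].
#' @param stage Stage to draw.
#' @return A ggplot.
#' @export
plot_correlation_heatmap <- function(records, stage) {
  m <- stage_cor_matrix(records, stage)
  ord <- correlation_cluster(m)
  genes <- ord$labels[ord$order]
  long <- tibble::as_tibble(as.data.frame(as.table(m)),
                            .name_repair = "minimal")
  names(long) <- c("gene_a", "gene_b", "r")
  long$gene_a <- factor(long$gene_a, levels = genes)
  long$gene_b <- factor(long$gene_b, levels = genes)
  ggplot2::ggplot(long, ggplot2::aes(.data$gene_a, .data$gene_b,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r", title = stage) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.stage_de <- function(object, from = "normal", to = "carcinoma",
                              ...) {
  folds <- object$pairwise |>
    dplyr::filter(.data$group_a == from, .data$group_b == to) |>
    dplyr::inner_join(dplyr::select(object$genes, "gene", "q_value"),
                      by = "gene")
  ggplot2::ggplot(folds,
                  ggplot2::aes(x = stats::reorder(.data$gene,
                                                  .data$fold_ratio_log2means),
                               y = .data$fold_ratio_log2means,
                               fill = .data$q_value < object$alpha)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("fold (", from, " to ", to, ")"),
                  fill = paste0("FDR < ", object$alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.classification_metrics <- function(object, ...) {
  long <- tibble::as_tibble(as.data.frame(as.table(object$confusion)))
  names(long) <- c("truth", "prediction", "proportion")
  ggplot2::ggplot(long, ggplot2::aes(.data$prediction, .data$truth,
                                     fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion)
    )) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param metrics A `classification_metrics` object.
#' @return A ggplot.
#' @export
plot_roc <- function(metrics) {
  ggplot2::ggplot(metrics$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                            colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.attribution_result <- function(object, class = "carcinoma", ...) {
  imp <- gene_importance(object, class)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("mean |SHAP| (", class, ")")) +
    ggplot2::theme_minimal()
}

#' Plot hub-target interaction importance
#'
#' @param interactions Tibble from [interaction_importance()].
#' @return A ggplot.
#' @export
plot_interaction_importance <- function(interactions) {
  ggplot2::ggplot(interactions, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |SHAP product|") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
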