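# A model interface for attribution: gradient of one class's output w.r.t.
# the inputs, plus the prediction itself. Trained classifiers are wrapped
# automatically; tests may supply a custom interface (e.g. a linear model).
as_attribution_model <- function(model) {
  if (inherits(model, "coupling_classifier")) {
    list(
      classes = model$classes,
      predict_fn = function(X) predict(model, X, type = "prob"),
      gradient_fn = function(X, class_index) {
        classifier_input_gradient(model, X, class_index)
      }
    )
  } else if (is.list(model) &&
               all(c("classes", "predict_fn", "gradient_fn") %in% names(model))) {
    model
  } else {
    abort("model must be a coupling_classifier or an attribution interface")
  }
}

#' Gradient-based Shapley value approximation (expected gradients)
#'
#' Approximates per-feature Shapley values by integrated gradients along
#' straight-line paths from randomly drawn background (reference) samples to
#' each explained sample: for each Monte-Carlo draw, a background row `b` and
#' a position `alpha ~ U(0, 1)` are sampled, and the contribution is
#' `grad f(b + alpha (x - b)) * (x - b)`. Averaging over `path_samples`
#' draws estimates the attribution; in expectation the attributions satisfy
#' local accuracy: their sum equals `f(x) - E_background f`.
#'
#' @param model A trained `coupling_classifier`, or a list with `classes`,
#'   `predict_fn(X)` and `gradient_fn(X, class_index)`.
#' @param background Numeric matrix of reference samples (samples x
#'   features), on the same standardized scale as `explained`.
#' @param explained Numeric matrix of samples to explain.
#' @param path_samples Monte-Carlo path draws per explained sample
#'   (default 200).
#' @param seed Integer seed; background draws and path positions are shared
#'   across classes.
#' @return An `attribution_result`: `shap` array (explained x features x
#'   classes), `fx` predictions for the explained samples, `f_baseline`
#'   mean background prediction per class, and the id metadata.
#' @export
gradient_shap <- function(model, background, explained,
                          path_samples = 200L, seed = 1L) {
  iface <- as_attribution_model(model)
  stopifnot(is.matrix(background), is.matrix(explained),
            ncol(background) == ncol(explained))
  if (nrow(background) == 0L) abort("background set is empty")
  n_exp <- nrow(explained)
  n_feat <- ncol(explained)
  classes <- iface$classes
  genes <- colnames(explained)
  if (is.null(genes)) genes <- paste0("x", seq_len(n_feat))

  set.seed(as.integer(seed))
  S <- as.integer(path_samples)
  bg_idx <- matrix(sample.int(nrow(background), n_exp * S, replace = TRUE),
                   n_exp, S)
  alpha <- matrix(runif(n_exp * S), n_exp, S)

  # assemble all path points in one block: rows grouped by draw then sample
  big_rows <- n_exp * S
  B <- background[as.vector(bg_idx), , drop = FALSE]
  Xrep <- explained[rep(seq_len(n_exp), times = S), , drop = FALSE]
  Arep <- as.vector(alpha)
  points <- B + Arep * (Xrep - B)
  diffs <- Xrep - B

  shap <- array(0, dim = c(n_exp, n_feat, length(classes)),
                dimnames = list(rownames(explained), genes, classes))
  for (ci in seq_along(classes)) {
    g <- iface$gradient_fn(points, ci)
    contrib <- g * diffs
    # average the S draws for each explained sample
    for (f in seq_len(n_feat)) {
      shap[, f, ci] <- rowMeans(matrix(contrib[, f], n_exp, S))
    }
  }

  fx <- iface$predict_fn(explained)
  f_baseline <- colMeans(iface$predict_fn(background))

  structure(
    list(
      shap = shap,
      genes = genes,
      classes = classes,
      background_ids = rownames(background),
      explained_ids = rownames(explained),
      fx = fx,
      f_baseline = f_baseline,
      path_samples = S,
      seed = as.integer(seed)
    ),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result>", dim(x$shap)[1], "samples x",
      dim(x$shap)[2], "features x", dim(x$shap)[3], "classes;",
      x$path_samples, "path samples\n")
  invisible(x)
}

#' Local-accuracy residuals of an attribution
#'
#' For each explained sample and class, the difference between the summed
#' attributions and `f(x) - mean_background f`; near zero when the
#' Monte-Carlo path integral has converged.
#'
#' @param result An `attribution_result`.
#' @return Tibble `sample`, `class`, `sum_shap`, `delta_f`, `residual`.
#' @export
local_accuracy <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  n <- dim(result$shap)[1]
  purrr::map_dfr(seq_along(result$classes), function(ci) {
    sums <- apply(result$shap[, , ci, drop = FALSE], 1, sum)
    delta <- result$fx[, ci] - result$f_baseline[ci]
    tibble::tibble(
      sample = if (is.null(result$explained_ids)) as.character(seq_len(n)) else result$explained_ids,
      class = result$classes[ci],
      sum_shap = sums, delta_f = delta, residual = sums - delta
    )
  })
}

#' Per-gene attribution importance
#'
#' Mean absolute Shapley value across the explained samples for one class,
#' ranked descending with ties broken by gene label.
#'
#' @param result An `attribution_result`.
#' @param class Class to summarise (default `"carcinoma"`).
#' @return Tibble `gene`, `importance`, `rank`.
#' @export
gene_importance <- function(result, class = "carcinoma") {
  stopifnot(inherits(result, "attribution_result"))
  ci <- match(class, result$classes)
  if (is.na(ci)) abort(paste0("unknown class: ", class))
  imp <- apply(abs(result$shap[, , ci, drop = FALSE]), 2, mean)
  out <- tibble::tibble(gene = result$genes, importance = as.numeric(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

#' Hub-target interaction importance
#'
#' For each hub-target pair, the mean over explained samples of the absolute
#' product of the two genes' Shapley values for the chosen class — high when
#' the two genes frequently carry jointly large contributions. Ranked
#' descending; the percentage gap between ranks 1 and 2 is attached.
#'
#' @param result An `attribution_result`.
#' @param hub Hub gene.
#' @param targets Target genes (default: every other gene in the result,
#'   the hub's 13 non-self partners on the full panel).
#' @param class Class to summarise (default `"carcinoma"`).
#' @return Tibble `hub`, `gene`, `pair`, `importance`, `rank`, with
#'   attribute `top_gap_pct`.
#' @export
interaction_importance <- function(result, hub, targets = NULL,
                                   class = "carcinoma") {
  stopifnot(inherits(result, "attribution_result"))
  ci <- match(class, result$classes)
  if (is.na(ci)) abort(paste0("unknown class: ", class))
  if (!(hub %in% result$genes)) abort(paste0("hub not in result: ", hub))
  if (is.null(targets)) targets <- setdiff(result$genes, hub)
  missing <- setdiff(targets, result$genes)
  if (length(missing) > 0) {
    abort(paste0("targets not in result: ", paste(missing, collapse = ", ")))
  }
  phi_hub <- result$shap[, hub, ci]
  out <- purrr::map_dfr(targets, function(g) {
    tibble::tibble(
      hub = hub, gene = g, pair = paste0(hub, "-", g),
      importance = mean(abs(phi_hub * result$shap[, g, ci]))
    )
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$gene)
  out$rank <- seq_len(nrow(out))
  gap <- if (nrow(out) >= 2L && out$importance[2] > 0) {
    100 * (out$importance[1] - out$importance[2]) / out$importance[2]
  } else {
    NA_real_
  }
  attr(out, "top_gap_pct") <- gap
  out
}

#' Long-format attribution table
#'
#' @param result An `attribution_result`.
#' @return Tibble `sample`, `gene`, `class`, `shap`.
#' @export
attribution_table <- function(result) {
  stopifnot(inherits(result, "attribution_result"))
  d <- dim(result$shap)
  ids <- if (is.null(result$explained_ids)) as.character(seq_len(d[1])) else result$explained_ids
  tidyr::expand_grid(
    class = result$classes, gene = result$genes, sample = ids
  ) |>
    dplyr::mutate(shap = as.vector(result$shap)) |>
    dplyr::select("sample", "gene", "class", "shap")
}
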