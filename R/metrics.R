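#' One-vs-rest ROC curve by threshold sweep
#'
#' Every distinct predicted score is used as a cut point (prediction positive
#' when score >= threshold), plus an infinite threshold anchoring (0, 0).
#'
#' @param scores Predicted probability of the positive class per sample.
#' @param positive Logical vector: is the sample truly positive?
#' @return Tibble `threshold`, `fpr`, `tpr` ordered by increasing fpr.
#' @export
roc_points <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC undefined without both positive and negative samples")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(thresholds, function(t) {
    pred <- scores >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(pred & !positive) / n_neg,
      tpr = sum(pred & positive) / n_pos
    )
  })
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc Tibble from [roc_points()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Evaluate a trained classifier on labelled data
#'
#' Accuracy, per-class precision/recall/F1, a row-normalized confusion
#' matrix, and one-vs-rest ROC curves with trapezoidal AUC. Classes absent
#' from the data get `NA` recall/AUC and are flagged.
#'
#' @param model A `coupling_classifier`.
#' @param x Numeric matrix (samples x features), standardized with training
#'   statistics.
#' @param y True stage labels.
#' @return A `classification_metrics` object: `accuracy`, `per_class`
#'   tibble, `confusion` (row-normalized), `confusion_counts`, `roc`
#'   (long tibble), `flagged_classes`.
#' @export
evaluate_classifier <- function(model, x, y) {
  y <- factor(y, levels = model$classes)
  if (length(y) == 0L) abort("empty evaluation set")
  probs <- predict(model, x, type = "prob")
  pred <- factor(model$classes[max.col(probs)], levels = model$classes)

  counts <- table(truth = y, prediction = pred)
  row_tot <- rowSums(counts)
  confusion <- sweep(unclass(counts), 1, ifelse(row_tot == 0, 1, row_tot), "/")

  flagged <- model$classes[row_tot[model$classes] == 0]
  per_class <- purrr::map_dfr(model$classes, function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      NA_real_
    } else {
      2 * precision * recall / (precision + recall)
    }
    auc <- if (cl %in% flagged || all(y == cl)) NA_real_ else {
      auc_trapezoid(roc_points(probs[, cl], y == cl))
    }
    tibble::tibble(class = cl, n = sum(y == cl), precision = precision,
                   recall = recall, f1 = f1, auc = auc)
  })

  roc_long <- purrr::map_dfr(setdiff(model$classes, flagged), function(cl) {
    if (all(y == cl)) return(NULL)
    dplyr::mutate(roc_points(probs[, cl], y == cl), class = cl,
                  .before = 1)
  })

  structure(
    list(
      accuracy = mean(pred == y),
      per_class = per_class,
      confusion = confusion,
      confusion_counts = unclass(counts),
      roc = roc_long,
      flagged_classes = flagged
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat("<classification_metrics> accuracy:", sprintf("%.4f", x$accuracy), "\n")
  print(x$per_class)
  invisible(x)
}
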