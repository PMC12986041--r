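#' One-way ANOVA across stages
#'
#' F is computed from the between/within mean-square decomposition
#' `F = MS_between / MS_within` with degrees of freedom `(k - 1, N - k)`;
#' the p-value is the upper tail of the corresponding F distribution.
#'
#' @param values_by_stage Named list mapping stage to a numeric vector.
#' @return Tibble `F_statistic`, `p_value`, `df_between`, `df_within`, plus a
#'   `degenerate` flag: when the within-group variance is exactly zero the
#'   p-value is 0 for unequal means and undefined (NA) for equal means.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2), b = c(3, 4)))
anova_oneway <- function(values_by_stage) {
  k <- length(values_by_stage)
  if (k < 2L) abort("need at least 2 groups")
  ns <- lengths(values_by_stage)
  if (any(ns < 2L)) abort("every group needs >= 2 samples")
  N <- sum(ns)
  means <- vapply(values_by_stage, mean, numeric(1))
  grand <- sum(unlist(values_by_stage)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(values_by_stage,
                          function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  if (ss_within == 0) {
    equal <- ss_between == 0
    return(tibble::tibble(
      F_statistic = if (equal) NA_real_ else Inf,
      p_value = if (equal) NA_real_ else 0,
      df_between = df_b, df_within = df_w, degenerate = TRUE
    ))
  }
  f_stat <- (ss_between / df_b) / (ss_within / df_w)
  tibble::tibble(
    F_statistic = f_stat,
    p_value = pf(f_stat, df_b, df_w, lower.tail = FALSE),
    df_between = df_b, df_within = df_w, degenerate = FALSE
  )
}

#' Tukey HSD post hoc comparisons
#'
#' For each group pair, the studentized-range statistic
#' `q = |mean1 - mean2| / sqrt(MS_within / 2 * (1/n1 + 1/n2))`
#' (the Tukey-Kramer form for unbalanced groups) with the adjusted p-value
#' from the studentized range distribution with parameters
#' `(k, N - k)`.
#'
#' @param values_by_stage Named list mapping stage to a numeric vector.
#' @return Tibble `group_a`, `group_b`, `diff` (mean_b - mean_a),
#'   `q_statistic`, `p_adjusted`.
#' @export
tukey_hsd <- function(values_by_stage) {
  k <- length(values_by_stage)
  if (k < 2L) abort("need at least 2 groups")
  ns <- lengths(values_by_stage)
  if (any(ns < 2L)) abort("every group needs >= 2 samples")
  N <- sum(ns)
  means <- vapply(values_by_stage, mean, numeric(1))
  ss_within <- sum(vapply(values_by_stage,
                          function(v) sum((v - mean(v))^2), numeric(1)))
  df_w <- N - k
  ms_within <- ss_within / df_w
  groups <- names(values_by_stage)
  combs <- utils::combn(seq_len(k), 2L)
  purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    if (ms_within == 0) {
      d <- unname(means[b] - means[a])
      return(tibble::tibble(
        group_a = groups[a], group_b = groups[b], diff = d,
        q_statistic = if (d == 0) 0 else Inf,
        p_adjusted = if (d == 0) 1 else 0
      ))
    }
    se <- sqrt(ms_within / 2 * (1 / ns[a] + 1 / ns[b]))
    q_stat <- unname(abs(means[a] - means[b]) / se)
    tibble::tibble(
      group_a = groups[a], group_b = groups[b],
      diff = unname(means[b] - means[a]),
      q_statistic = q_stat,
      p_adjusted = ptukey(q_stat, nmeans = k, df = df_w, lower.tail = FALSE)
    )
  })
}

#' Linear-scale fold-change from log2 means
#'
#' `2^(mean_to - mean_from)`: values above 1 indicate upregulation in the
#' second condition.
#'
#' @param mean_from,mean_to Log2-scale means.
#' @return Positive ratio.
#' @export
fold_change <- function(mean_from, mean_to) 2^(mean_to - mean_from)

#' Stage-wise differential expression for every gene
#'
#' Per gene: one-way ANOVA across the stages with BH adjustment across genes;
#' Tukey HSD for all stage pairs (run for every gene, with a `post_hoc_run`
#' flag marking the genes whose ANOVA q-value is below `alpha`, mirroring a
#' post-hoc-only-when-significant workflow); per-pair fold-changes on the
#' `2^delta` definition plus the plain ratio of log2 means
#' (`fold_ratio_log2means`), reported because published fold values are
#' sometimes quoted on that scale.
#'
#' @param expr Expression tibble (log2 scale).
#' @param annotation Annotation with `sample_id`, `stage`.
#' @param alpha FDR threshold gating the post hoc flag (default 0.05).
#' @return Object of class `stage_de`: list with `genes` (per-gene ANOVA
#'   tibble incl. stage means) and `pairwise` (per gene and stage pair).
#' @export
differential_expression <- function(expr, annotation, alpha = 0.05) {
  m <- validate_expression(expr, annotation)
  annotation <- annotation[match(colnames(m), annotation$sample_id), ]
  stages <- intersect(stage_levels(), unique(annotation$stage))
  split_ids <- lapply(stages, function(s) annotation$sample_id[annotation$stage == s])
  names(split_ids) <- stages

  genes_tbl <- purrr::map_dfr(rownames(m), function(g) {
    vals <- lapply(split_ids, function(ids) m[g, ids])
    a <- anova_oneway(vals)
    row <- tibble::tibble(gene = g)
    for (s in stages) {
      row[[paste0("mean_", s)]] <- mean(vals[[s]])
      row[[paste0("n_", s)]] <- length(vals[[s]])
    }
    dplyr::bind_cols(row, a)
  })
  genes_tbl$q_value <- bh_fdr(genes_tbl$p_value)

  pairwise <- purrr::map_dfr(rownames(m), function(g) {
    vals <- lapply(split_ids, function(ids) m[g, ids])
    tk <- tukey_hsd(vals)
    tk$gene <- g
    tk$fold_change <- fold_change(
      vapply(tk$group_a, function(s) mean(vals[[s]]), numeric(1)),
      vapply(tk$group_b, function(s) mean(vals[[s]]), numeric(1))
    )
    tk$fold_ratio_log2means <- vapply(seq_len(nrow(tk)), function(i) {
      mean(vals[[tk$group_b[i]]]) / mean(vals[[tk$group_a[i]]])
    }, numeric(1))
    dplyr::relocate(tk, "gene")
  })
  pairwise <- dplyr::left_join(
    pairwise,
    dplyr::transmute(genes_tbl, gene = .data$gene,
                     post_hoc_run = .data$q_value < alpha),
    by = "gene"
  )

  structure(list(genes = genes_tbl, pairwise = pairwise, alpha = alpha),
            class = "stage_de")
}

#' @export
print.stage_de <- function(x, ...) {
  cat("<stage_de>", nrow(x$genes), "genes;",
      sum(x$genes$q_value < x$alpha), "significant at FDR", x$alpha, "\n")
  invisible(x)
}

#' Per-category mean fold-change
#'
#' Arithmetic mean of the genes' normal-to-carcinoma fold-changes within each
#' functional category.
#'
#' @param de A `stage_de` object or a tibble with columns `gene` and `fold`.
#' @param categories Tibble `gene`, `category` covering every gene (default
#'   [panel_categories()]).
#' @param from,to Stage pair defining the fold (defaults normal ->
#'   carcinoma).
#' @param fold_column Which fold definition to average when `de` is a
#'   `stage_de`: `"fold_ratio_log2means"` (default, the scale on which
#'   published panel folds are quoted) or `"fold_change"` (`2^delta`).
#' @return Tibble `category`, `mean_fold`, `n_genes`.
#' @export
category_summary <- function(de, categories = panel_categories(),
                             from = "normal", to = "carcinoma",
                             fold_column = "fold_ratio_log2means") {
  if (inherits(de, "stage_de")) {
    folds <- de$pairwise |>
      dplyr::filter(.data$group_a == from, .data$group_b == to) |>
      dplyr::transmute(gene = .data$gene, fold = .data[[fold_column]])
  } else {
    stopifnot(all(c("gene", "fold") %in% names(de)))
    folds <- de
  }
  uncat <- setdiff(folds$gene, categories$gene)
  if (length(uncat) > 0) {
    abort(paste0("uncategorized gene(s): ", paste(uncat, collapse = ", ")))
  }
  folds |>
    dplyr::inner_join(categories, by = "gene") |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_fold = mean(.data$fold), n_genes = dplyr::n(),
                     .groups = "drop")
}
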