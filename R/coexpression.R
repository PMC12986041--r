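#' Pearson correlation with a zero-correlation t-test
#'
#' Computes the sample Pearson coefficient from its cross-product form and a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3L) abort("need at least 3 samples")
  dx <- x - mean(x)
  dy <- y - mean(y)
  if (all(dx == 0) || all(dy == 0)) {
    abort("correlation undefined for a constant vector")
  }
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, p_value = p, n = n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values: monotone in the p-value ranks, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}

#' Stage-stratified pairwise correlation table
#'
#' One record per unordered gene pair (91 for the 14-gene panel) per stage,
#' with Pearson r, R-squared, two-sided p, and BH q-values adjusted
#' separately within each stage across all pairs.
#'
#' @param expr Expression tibble.
#' @param annotation Annotation tibble with `sample_id`, `stage`.
#' @param stages Stages to tabulate (default all three, in canonical order).
#' @return Tibble `gene_a`, `gene_b`, `stage`, `r`, `r_squared`, `p_value`,
#'   `q_value`, `n`, with `gene_a < gene_b` under the panel gene ordering.
#' @export
stage_correlation_table <- function(expr, annotation,
                                    stages = stage_levels()) {
  m <- validate_expression(expr, annotation)
  genes <- rownames(m)
  missing_stage <- setdiff(stages, unique(annotation$stage))
  if (length(missing_stage) > 0) {
    abort(paste0("stage(s) absent from annotation: ",
                 paste(missing_stage, collapse = ", ")))
  }
  pairs <- t(utils::combn(genes, 2L))

  purrr::map_dfr(stages, function(s) {
    ids <- annotation$sample_id[annotation$stage == s]
    if (length(ids) < 3L) abort(paste0("stage ", s, " has < 3 samples"))
    sub <- m[, ids, drop = FALSE]
    rec <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      pr <- pearson_r(sub[pairs[i, 1], ], sub[pairs[i, 2], ])
      tibble::tibble(
        gene_a = pairs[i, 1], gene_b = pairs[i, 2], stage = s,
        r = pr$r, r_squared = pr$r^2, p_value = pr$p_value, n = pr$n
      )
    })
    rec$q_value <- bh_fdr(rec$p_value)
    dplyr::relocate(rec, "q_value", .after = "p_value")
  })
}

pair_lookup <- function(records, gene_a, gene_b, stage) {
  hit <- records[
    ((records$gene_a == gene_a & records$gene_b == gene_b) |
       (records$gene_a == gene_b & records$gene_b == gene_a)) &
      records$stage == stage, ]
  if (nrow(hit) == 0L) {
    abort(paste0("missing correlation record: ", gene_a, "-", gene_b,
                 " @ ", stage))
  }
  hit[1, ]
}

#' Hub coupling summary across stages
#'
#' Mean R-squared between a hub gene and its designated targets within each
#' stage, plus overall (carcinoma/normal) and per-transition fold ratios of
#' the stage means.
#'
#' @param records Correlation table from [stage_correlation_table()].
#' @param hub Hub gene.
#' @param targets Target genes (default [hub_targets()] of the hub).
#' @param stages Ordered stages.
#' @return Tibble with one row per stage (`mean_r2`) and attributes folded
#'   into columns: `overall_fold` (last/first stage mean) and
#'   `transition_fold` (vs previous stage; NA for the first). Fold ratios are
#'   `NA` when the denominator mean is zero.
#' @export
hub_coupling_summary <- function(records, hub, targets = NULL,
                                 stages = stage_levels()) {
  if (is.null(targets)) targets <- hub_targets(hub, unique(c(records$gene_a, records$gene_b)))
  per_stage <- purrr::map_dbl(stages, function(s) {
    mean(purrr::map_dbl(targets, function(t) {
      pair_lookup(records, hub, t, s)$r_squared
    }))
  })
  first <- per_stage[1]
  fold_of <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    hub = hub,
    stage = stages,
    mean_r2 = per_stage,
    transition_fold = c(NA_real_, purrr::map2_dbl(
      per_stage[-1], per_stage[-length(per_stage)], fold_of
    )),
    overall_fold = fold_of(per_stage[length(per_stage)], first)
  )
}

#' Divergence ratio between two hubs
#'
#' Ratio of the two hubs' mean target R-squared within each stage (for the
#' DDR receptors: how many-fold stronger DDR2's coupling is than DDR1's).
#'
#' @param records Correlation table.
#' @param hub_num,hub_den Numerator and denominator hub genes.
#' @param stages Ordered stages.
#' @return Tibble `stage`, `ratio`.
#' @export
hub_divergence <- function(records, hub_num, hub_den,
                           stages = stage_levels()) {
  genes <- unique(c(records$gene_a, records$gene_b))
  num <- hub_coupling_summary(records, hub_num,
                              hub_targets(hub_num, genes), stages)
  den <- hub_coupling_summary(records, hub_den,
                              hub_targets(hub_den, genes), stages)
  tibble::tibble(
    stage = stages,
    ratio = ifelse(den$mean_r2 == 0, NA_real_, num$mean_r2 / den$mean_r2)
  )
}

classify_kinetics <- function(r2, floor, de_novo_min = 0.3) {
  first <- r2[1]
  last <- r2[length(r2)]
  if (first < floor && last >= de_novo_min) return("de_novo")
  if (first >= floor && all(diff(r2) > 0)) return("progressive")
  if (last < first) return("declining")
  "flat"
}

#' Coupling trajectory of one gene pair across stages
#'
#' Collects the pair's R-squared across the ordered stages and derives
#' per-transition and overall deltas, fold ratios (suppressed when the
#' denominator is below `ratio_floor` to avoid unstable near-zero ratios),
#' and a kinetic class: `de_novo` (baseline below `near_zero_floor`,
#' carcinoma >= 0.3), `progressive` (monotone increase from a detectable
#' baseline), `declining` (final below baseline), else `flat`.
#'
#' @param records Correlation table.
#' @param gene_a,gene_b The pair.
#' @param near_zero_floor Baseline R-squared below which a start counts as
#'   "near zero" (default 0.05).
#' @param ratio_floor Denominator floor below which fold ratios are reported
#'   as `NA` (default 0.001).
#' @param stages Ordered stages.
#' @return One-row tibble: `gene_a`, `gene_b`, per-stage `r2_*` columns,
#'   `delta_*` and `fold_*` per transition, `delta_overall`, `fold_overall`,
#'   `kinetic_class`.
#' @export
coupling_trajectory <- function(records, gene_a, gene_b,
                                near_zero_floor = 0.05,
                                ratio_floor = 0.001,
                                stages = stage_levels()) {
  r2 <- purrr::map_dbl(stages, function(s) {
    pair_lookup(records, gene_a, gene_b, s)$r_squared
  })
  names(r2) <- stages
  deltas <- diff(r2)
  folds <- purrr::map2_dbl(r2[-1], r2[-length(r2)], function(num, den) {
    if (den < ratio_floor) NA_real_ else num / den
  })
  trans <- paste0(stages[-length(stages)], "_to_", stages[-1])
  out <- tibble::tibble(gene_a = gene_a, gene_b = gene_b)
  for (i in seq_along(stages)) out[[paste0("r2_", stages[i])]] <- unname(r2[i])
  for (i in seq_along(trans)) out[[paste0("delta_", trans[i])]] <- unname(deltas[i])
  out$delta_overall <- unname(r2[length(r2)] - r2[1])
  for (i in seq_along(trans)) out[[paste0("fold_", trans[i])]] <- unname(folds[i])
  out$fold_overall <- if (r2[1] < ratio_floor) NA_real_ else unname(r2[length(r2)] / r2[1])
  out$kinetic_class <- classify_kinetics(r2, near_zero_floor)
  out
}

#' Trajectories for many pairs at once
#'
#' @param records Correlation table covering all requested stages.
#' @param pairs Optional two-column data frame (`gene_a`, `gene_b`); default
#'   every pair present in `records`.
#' @inheritParams coupling_trajectory
#' @return Tibble with one row per pair, as [coupling_trajectory()].
#' @export
coupling_trajectories <- function(records, pairs = NULL,
                                  near_zero_floor = 0.05,
                                  ratio_floor = 0.001,
                                  stages = stage_levels()) {
  if (is.null(pairs)) {
    pairs <- dplyr::distinct(records, .data$gene_a, .data$gene_b)
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    coupling_trajectory(records, pairs$gene_a[i], pairs$gene_b[i],
                        near_zero_floor, ratio_floor, stages)
  })
}

#' Average-linkage clustering on correlation distance
#'
#' Agglomerative clustering of genes with distance `d = 1 - |r|`, which
#' treats positive and negative correlation symmetrically. Genes are ordered
#' lexicographically before agglomeration so that equal-height merges resolve
#' deterministically by the smallest gene-pair label.
#'
#' @param cor_matrix Square symmetric correlation matrix with unit diagonal
#'   and gene dimnames.
#' @return An `hclust` tree (average linkage).
#' @export
correlation_cluster <- function(cor_matrix) {
  stopifnot(is.matrix(cor_matrix), nrow(cor_matrix) == ncol(cor_matrix))
  if (max(abs(cor_matrix - t(cor_matrix))) > 1e-12) {
    abort("correlation matrix must be symmetric")
  }
  if (max(abs(diag(cor_matrix) - 1)) > 1e-12) {
    abort("correlation matrix must have unit diagonal")
  }
  genes <- rownames(cor_matrix)
  ord <- order(genes)
  d <- 1 - abs(cor_matrix[ord, ord])
  hclust(as.dist(d), method = "average")
}

#' Correlation matrix for one stage from the long-format table
#'
#' @param records Correlation table.
#' @param stage Stage to extract.
#' @param genes Gene ordering (default: sorted union of pair members).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
stage_cor_matrix <- function(records, stage, genes = NULL) {
  rec <- records[records$stage == stage, ]
  if (is.null(genes)) genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
  m <- diag(1, length(genes))
  dimnames(m) <- list(genes, genes)
  for (i in seq_len(nrow(rec))) {
    m[rec$gene_a[i], rec$gene_b[i]] <- rec$r[i]
    m[rec$gene_b[i], rec$gene_a[i]] <- rec$r[i]
  }
  m
}

#' Write a dendrogram in Newick format
#'
#' @param tree An `hclust` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
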