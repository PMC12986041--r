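#' Aggregate probe-level expression to gene level
#'
#' Probes mapping to more than one gene are excluded to avoid ambiguity;
#' multiple probes mapping to the same gene are averaged element-wise.
#'
#' @param probe_expr Tibble: first column `probe_id`, remaining columns
#'   samples.
#' @param probe_map Tibble with columns `probe_id`, `gene_symbol`; entries
#'   mapping a probe to several genes carry all symbols in one field
#'   separated by `delim`.
#' @param delim Delimiter for multi-gene map entries (Affymetrix-style
#'   `"///"` by default).
#' @return List: `expression` (gene-level tibble, sample order conserved),
#'   `dropped_probes` (multi-gene probes), `dropped_genes` (genes whose every
#'   probe was ambiguous).
#' @export
aggregate_probes <- function(probe_expr, probe_map, delim = "///") {
  stopifnot("probe_id" %in% names(probe_expr),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  probe_map <- dplyr::distinct(probe_map, .data$probe_id, .data$gene_symbol)
  missing <- setdiff(probe_expr$probe_id, probe_map$probe_id)
  if (length(missing) > 0) {
    abort(paste0("probe_map does not cover probes: ",
                 paste(head(missing, 5), collapse = ", ")))
  }

  map <- probe_map |>
    dplyr::filter(.data$probe_id %in% probe_expr$probe_id) |>
    dplyr::mutate(genes = strsplit(.data$gene_symbol, delim, fixed = TRUE),
                  genes = purrr::map(.data$genes, trimws),
                  n_genes = lengths(.data$genes))
  multi <- dplyr::filter(map, .data$n_genes > 1L)
  keep <- dplyr::filter(map, .data$n_genes == 1L) |>
    dplyr::mutate(gene = purrr::map_chr(.data$genes, 1))

  all_genes <- unique(unlist(map$genes))
  surviving_genes <- unique(keep$gene)
  dropped_genes <- setdiff(all_genes, surviving_genes)

  sample_cols <- setdiff(names(probe_expr), "probe_id")
  m <- as.matrix(probe_expr[sample_cols])
  rownames(m) <- probe_expr$probe_id
  rows <- lapply(surviving_genes, function(g) {
    probes <- keep$probe_id[keep$gene == g]
    colMeans(m[probes, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- surviving_genes

  list(
    expression = expr_tibble(out),
    dropped_probes = multi$probe_id,
    dropped_genes = dropped_genes
  )
}

#' Empirical-Bayes location/scale batch correction
#'
#' Implements the parametric ComBat-style model
#' `Y = alpha + X beta + gamma + sqrt(delta) * eps`: a gene-wise linear model
#' with the disease stage as a biological covariate to preserve, per-batch
#' additive (`gamma`) and multiplicative (`delta`) effects estimated on
#' standardized residuals, shrunk with moment-matched parametric priors
#' (normal on gamma, inverse-gamma on delta), then removed with the stage
#' signal added back.
#'
#' @param expr Expression tibble (`gene_id` + sample columns, log2 scale).
#' @param annotation Tibble `sample_id`, `stage`, `batch` covering every
#'   sample.
#' @param parametric Use the parametric (closed-form prior) shrinkage; the
#'   only supported mode.
#' @return List: `corrected` expression tibble and `model`, a `batch_model`
#'   holding gene-wise means, stage coefficients, raw and shrunk batch
#'   effects, and prior hyperparameters. Genes with zero residual variance
#'   are left uncorrected and listed in `model$flagged_genes`.
#' @export
correct_batch_effects <- function(expr, annotation, parametric = TRUE) {
  if (!parametric) abort("only parametric shrinkage is implemented")
  m <- validate_expression(expr, annotation)
  annotation <- annotation[match(colnames(m), annotation$sample_id), ]
  batch <- factor(annotation$batch)
  stage <- factor(annotation$stage, levels = stage_levels())

  if (nlevels(batch) < 2L) {
    warn("single batch: returning data unchanged")
    return(list(corrected = expr, model = NULL))
  }
  if (any(table(batch) < 2L)) abort("every batch must contain >= 2 samples")

  n_array <- ncol(m)
  batch_design <- model.matrix(~ 0 + batch)
  stage_design <- model.matrix(~ stage)[, -1, drop = FALSE]
  # drop stage columns confounded with batch (rank does not increase)
  keep <- logical(ncol(stage_design))
  acc <- batch_design
  for (j in seq_len(ncol(stage_design))) {
    cand <- cbind(acc, stage_design[, j])
    if (qr(cand)$rank > qr(acc)$rank) {
      keep[j] <- TRUE
      acc <- cand
    }
  }
  stage_design <- stage_design[, keep, drop = FALSE]
  design <- cbind(batch_design, stage_design)

  n_batches <- table(batch)
  B_hat <- solve(crossprod(design), crossprod(design, t(m)))
  grand_mean <- as.numeric(n_batches / n_array) %*%
    B_hat[seq_len(nlevels(batch)), , drop = FALSE]
  resid <- m - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)

  flagged <- rownames(m)[var_pooled <= .Machine$double.eps]
  active <- setdiff(rownames(m), flagged)

  stand_mean <- matrix(grand_mean, nrow = nrow(m), ncol = n_array,
                       byrow = FALSE)
  rownames(stand_mean) <- rownames(m)
  tmp <- design
  tmp[, seq_len(nlevels(batch))] <- 0
  stand_mean <- stand_mean + t(tmp %*% B_hat)

  s_data <- (m - stand_mean) / sqrt(var_pooled)

  batches_idx <- split(seq_len(n_array), batch)
  gamma_hat <- vapply(batches_idx, function(idx) {
    rowMeans(s_data[, idx, drop = FALSE])
  }, numeric(nrow(m)))
  delta_hat <- vapply(batches_idx, function(idx) {
    apply(s_data[, idx, drop = FALSE], 1, var)
  }, numeric(nrow(m)))

  # moment-matched hyperparameters per batch (across genes)
  gamma_bar <- colMeans(gamma_hat[active, , drop = FALSE])
  tau2 <- apply(gamma_hat[active, , drop = FALSE], 2, var)
  a_prior <- apply(delta_hat[active, , drop = FALSE], 2, function(d) {
    m1 <- mean(d); s2 <- var(d)
    (2 * s2 + m1^2) / s2
  })
  b_prior <- apply(delta_hat[active, , drop = FALSE], 2, function(d) {
    m1 <- mean(d); s2 <- var(d)
    (m1 * s2 + m1^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (bi in seq_along(batches_idx)) {
    idx <- batches_idx[[bi]]
    n_b <- length(idx)
    sd_b <- s_data[active, idx, drop = FALSE]
    g_hat <- gamma_hat[active, bi]
    d_old <- delta_hat[active, bi]
    g_new <- g_hat
    repeat {
      g_new <- (n_b * tau2[bi] * g_hat + d_old * gamma_bar[bi]) /
        (n_b * tau2[bi] + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[bi]) / (n_b / 2 + a_prior[bi] - 1)
      conv <- max(abs(d_new - d_old) / abs(d_old))
      d_old <- d_new
      if (conv < 1e-4) break
    }
    gamma_star[active, bi] <- g_new
    delta_star[active, bi] <- d_old
  }

  adjusted <- s_data
  for (bi in seq_along(batches_idx)) {
    idx <- batches_idx[[bi]]
    adjusted[active, idx] <-
      (s_data[active, idx, drop = FALSE] - gamma_star[active, bi]) /
      sqrt(delta_star[active, bi])
  }
  corrected <- adjusted * sqrt(var_pooled) + stand_mean
  corrected[flagged, ] <- m[flagged, , drop = FALSE]

  model <- structure(
    list(
      genes = rownames(m),
      batches = levels(batch),
      overall_mean = as.numeric(grand_mean),
      stage_coefficients = t(B_hat[-seq_len(nlevels(batch)), , drop = FALSE]),
      additive_batch = gamma_hat,
      multiplicative_batch = delta_hat,
      additive_batch_shrunk = gamma_star,
      multiplicative_batch_shrunk = delta_star,
      prior_parameters = tibble::tibble(
        batch = levels(batch), gamma_bar = gamma_bar, tau2 = tau2,
        a_prior = a_prior, b_prior = b_prior
      ),
      var_pooled = var_pooled,
      flagged_genes = flagged
    ),
    class = "batch_model"
  )

  list(corrected = expr_tibble(corrected), model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat("<batch_model>", length(x$genes), "genes,",
      length(x$batches), "batches\n")
  if (length(x$flagged_genes)) {
    cat("  flagged (uncorrected):", paste(x$flagged_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coefficient-of-variation quality report
#'
#' CV = sd/mean per gene on the log2-scale values (sample sd, n-1
#' denominator), computed across all samples. Genes with CV at or below
#' `threshold`, or with an undefined CV (zero mean), are flagged; nothing is
#' removed.
#'
#' @param expr Expression tibble.
#' @param threshold Flagging threshold on the CV (default 0.2).
#' @return Tibble `gene`, `mean`, `sd`, `cv`, `flagged`.
#' @export
qc_cv <- function(expr, threshold = 0.2) {
  m <- validate_expression(expr)
  if (nrow(m) == 0) abort("empty expression matrix")
  mu <- unname(rowMeans(m))
  s <- unname(apply(m, 1, sd))
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  tibble::tibble(
    gene = rownames(m), mean = mu, sd = s, cv = cv,
    flagged = is.na(cv) | cv <= threshold
  )
}

#' Train-statistics standardization
#'
#' `fit_standardizer()` learns per-gene means and standard deviations from
#' the training samples only; `apply_standardizer()` applies
#' `(x - mu) / sigma` with those frozen statistics to any sample set, so
#' validation and test data never leak into the scaling.
#'
#' @param expr Expression tibble.
#' @param sample_ids Training sample ids (default: all columns of `expr`).
#' @return `fit_standardizer()`: a `standardizer` with `means` and `sds`;
#'   `apply_standardizer()`: a standardized expression tibble;
#'   `unstandardize()`: the inverse transform.
#' @export
fit_standardizer <- function(expr, sample_ids = NULL) {
  m <- validate_expression(expr)
  if (!is.null(sample_ids)) {
    stopifnot(all(sample_ids %in% colnames(m)))
    m <- m[, sample_ids, drop = FALSE]
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    abort(paste0("zero standard deviation for gene(s): ",
                 paste(rownames(m)[s == 0], collapse = ", ")))
  }
  structure(list(genes = rownames(m), means = mu, sds = s),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer A fitted `standardizer`.
#' @export
apply_standardizer <- function(standardizer, expr) {
  stopifnot(inherits(standardizer, "standardizer"))
  m <- validate_expression(expr)
  stopifnot(identical(rownames(m), standardizer$genes))
  expr_tibble((m - standardizer$means) / standardizer$sds)
}

#' @rdname fit_standardizer
#' @export
unstandardize <- function(standardizer, expr) {
  stopifnot(inherits(standardizer, "standardizer"))
  m <- validate_expression(expr)
  stopifnot(identical(rownames(m), standardizer$genes))
  expr_tibble(m * standardizer$sds + standardizer$means)
}

#' Silhouette diagnostic for batch-correction efficacy
#'
#' Mean silhouette width of samples (Euclidean distance on gene-standardized
#' expression) when grouped by batch versus by stage. After successful
#' correction, grouping by stage should dominate grouping by batch; no
#' pass/fail threshold is imposed.
#'
#' @param expr Expression tibble.
#' @param annotation Annotation tibble with `stage` and `batch`.
#' @return Tibble `grouping`, `mean_silhouette`.
#' @export
silhouette_diagnostic <- function(expr, annotation) {
  if (!requireNamespace("cluster", quietly = TRUE)) {
    abort("silhouette_diagnostic requires the 'cluster' package")
  }
  m <- validate_expression(expr, annotation)
  annotation <- annotation[match(colnames(m), annotation$sample_id), ]
  z <- t(scale(t(m)))
  d <- stats::dist(t(z))
  mean_sil <- function(labels) {
    f <- as.integer(factor(labels))
    if (length(unique(f)) < 2L) return(NA_real_)
    mean(cluster::silhouette(f, d)[, "sil_width"])
  }
  tibble::tibble(
    grouping = c("batch", "stage"),
    mean_silhouette = c(mean_sil(annotation$batch), mean_sil(annotation$stage))
  )
}
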