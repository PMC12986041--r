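#' Solve the hub-target coupling slope for a planted R-squared
#'
#' Under the latent linear model `target = intercept + beta * hub + noise`,
#' the population coefficient of determination between hub and target is
#' `R2 = beta^2 * var_hub / (beta^2 * var_hub + var_noise)`. This inverts that
#' relation so a requested R-squared is planted exactly in expectation.
#'
#' @param target_r2 Desired squared correlation, in `[0, 1)`.
#' @param hub_variance Variance of the hub gene's expression (> 0).
#' @param noise_variance Residual variance of the target (> 0).
#' @return Non-negative slope `beta`.
#' @export
#' @examples
#' coupling_slope(0.549, 1, 1) # sqrt(0.549 / 0.451)
coupling_slope <- function(target_r2, hub_variance, noise_variance) {
  if (!is.numeric(target_r2) || target_r2 < 0 || target_r2 >= 1) {
    abort("target_r2 must lie in [0, 1)")
  }
  if (hub_variance <= 0 || noise_variance <= 0) {
    abort("hub_variance and noise_variance must be positive")
  }
  sqrt(target_r2 / (1 - target_r2) * noise_variance / hub_variance)
}

# Default per-stage mean log2 expression. COL11A1, MMP11 and DDR2 means are
# the printed stage values; the remaining genes respect the printed
# normal-to-carcinoma fold-changes (as ratios of log2 means) with
# intermediate adenoma values.
default_stage_means <- function() {
  m <- tibble::tribble(
    ~gene,     ~normal, ~adenoma, ~carcinoma,
    "DDR1",       7.50,     7.60,       7.80,
    "DDR2",       7.21,     5.74,       6.57,
    "COL1A1",     7.50,     8.50,       9.20,
    "COL1A2",     7.80,     8.30,       9.05,
    "COL3A1",     7.60,     8.40,       9.00,
    "COL5A1",     7.20,     7.70,       8.40,
    "COL5A2",     7.00,     7.50,       8.26,
    "COL11A1",    3.61,     4.84,       7.18,
    "FN1",        7.50,     8.10,       8.70,
    "MMP1",       4.50,     6.30,       8.10,
    "MMP2",       7.60,     7.65,       7.83,
    "MMP7",       4.20,     6.30,       8.15,
    "MMP9",       4.80,     6.00,       8.35,
    "MMP11",      5.28,     5.83,       7.85
  )
  tidyr::pivot_longer(m, -"gene", names_to = "stage", values_to = "mean")
}

# Default planted hub (DDR2) coupling R-squared per target and stage. The
# five pairs with printed trajectories carry those values; the remaining
# seven targets are filled so the per-stage mean over the 12 non-receptor
# targets is exactly 0.147 / 0.234 / 0.380. DDR1's planted coupling is set so
# its induced mean target R-squared reproduces 0.031 / 0.021 / 0.017.
default_planted_r2 <- function() {
  m <- tibble::tribble(
    ~gene,     ~normal, ~adenoma, ~carcinoma,
    "DDR1",      0.210,    0.090,      0.045,
    "COL1A1",    0.120,    0.318,      0.541,
    "COL1A2",    0.280,    0.300,      0.380,
    "COL3A1",    0.250,    0.280,      0.360,
    "COL5A1",    0.200,    0.220,      0.300,
    "COL5A2",    0.325,    0.384,      0.577,
    "COL11A1",   0.006,    0.235,      0.549,
    "FN1",       0.180,    0.200,      0.300,
    "MMP1",      0.080,    0.120,      0.220,
    "MMP2",      0.050,    0.269,      0.548,
    "MMP7",      0.060,    0.100,      0.200,
    "MMP9",      0.203,    0.194,      0.226,
    "MMP11",     0.010,    0.188,      0.359
  )
  tidyr::pivot_longer(m, -"gene", names_to = "stage", values_to = "r2")
}

# Default within-stage total standard deviation per gene. High-fold
# "activation" genes have concentrated within-stage spread; near-flat genes a
# wider one, so every pooled coefficient of variation exceeds 0.2.
default_total_sd <- function() {
  tight <- c("COL11A1", "MMP1", "MMP7", "MMP9", "MMP11")
  genes <- setdiff(panel_genes(), "DDR2")
  tibble::tibble(gene = genes, sd = ifelse(genes %in% tight, 0.9, 1.7))
}

#' Specification of a synthetic stage-stratified expression study
#'
#' Builds the full parameter set for [simulate_expression()]. Defaults
#' reproduce the statistical structure of the 680-sample colorectal study:
#' three stages (n = 158/170/352), the 14-gene panel with DDR2 as hub, planted
#' hub-target R-squared trajectories (e.g. COL11A1 0.006 -> 0.235 -> 0.549),
#' per-gene stage means respecting the printed fold-changes, and five
#' pseudo-batches with additive and multiplicative effects.
#'
#' @param genes Ordered gene identifiers (default the 14-gene panel).
#' @param hub Hub gene driving the planted coupling (default `"DDR2"`).
#' @param stage_sizes Named integer vector of samples per stage.
#' @param stage_means Tibble `gene`, `stage`, `mean` covering every
#'   gene/stage.
#' @param hub_variance Named per-stage variance of the hub's expression.
#' @param planted_r2 Tibble `gene`, `stage`, `r2` for every non-hub gene;
#'   values in `[0, 1)`.
#' @param noise_variance Tibble `gene`, `stage`, `var` of target residual
#'   variance; by default derived from per-gene total sds so that the target's
#'   total within-stage variance is `total_sd^2` at the planted R-squared.
#' @param batch_count Number of pseudo-batches (>= 1).
#' @param batch_additive Per-batch additive shifts (gamma), recycled across
#'   genes, or a tibble `gene`, `batch`, `gamma`.
#' @param batch_multiplicative Per-batch residual variance scales (delta > 0),
#'   recycled across genes, or a tibble `gene`, `batch`, `delta`.
#' @param bimodal Optional two-component mixture for named genes:
#'   `list(genes =, weight =, separation =)`. Default off.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `coupling_spec`.
#' @export
synthetic_spec <- function(genes = panel_genes(),
                           hub = "DDR2",
                           stage_sizes = c(normal = 158L, adenoma = 170L,
                                           carcinoma = 352L),
                           stage_means = default_stage_means(),
                           hub_variance = c(normal = 1.5625,
                                            adenoma = 1.5625,
                                            carcinoma = 1.5625),
                           planted_r2 = default_planted_r2(),
                           noise_variance = NULL,
                           batch_count = 5L,
                           batch_additive = c(-0.8, -0.4, 0, 0.4, 0.8),
                           batch_multiplicative = c(1.4, 0.8, 1, 1.25, 0.7),
                           bimodal = NULL,
                           seed = 1L) {
  stages <- stage_levels()
  stopifnot(
    is.character(genes), !anyDuplicated(genes), hub %in% genes,
    setequal(names(stage_sizes), stages)
  )
  if (any(stage_sizes <= 0)) abort("stage_sizes must be positive")
  if (any(hub_variance <= 0)) abort("hub_variance must be positive")
  stopifnot(setequal(names(hub_variance), stages))

  targets <- setdiff(genes, hub)
  stage_means <- dplyr::select(stage_means, "gene", "stage", "mean")
  need <- tidyr::expand_grid(gene = genes, stage = stages)
  if (nrow(dplyr::anti_join(need, stage_means, by = c("gene", "stage"))) > 0) {
    abort("stage_means must cover every (gene, stage)")
  }
  if (hub %in% planted_r2$gene) {
    abort("hub must not appear in planted_r2")
  }
  need_t <- tidyr::expand_grid(gene = targets, stage = stages)
  if (nrow(dplyr::anti_join(need_t, planted_r2, by = c("gene", "stage"))) > 0) {
    abort("planted_r2 must cover every (target gene, stage)")
  }
  if (any(planted_r2$r2 < 0) || any(planted_r2$r2 >= 1)) {
    abort("planted_r2 values must lie in [0, 1)")
  }

  if (is.null(noise_variance)) {
    noise_variance <- planted_r2 |>
      dplyr::left_join(default_total_sd(), by = "gene") |>
      dplyr::mutate(
        sd = dplyr::coalesce(.data$sd, 1.2),
        var = .data$sd^2 * (1 - .data$r2)
      ) |>
      dplyr::select("gene", "stage", "var")
  }
  if (nrow(dplyr::anti_join(need_t, noise_variance, by = c("gene", "stage"))) > 0) {
    abort("noise_variance must cover every (target gene, stage)")
  }
  if (any(noise_variance$var <= 0)) abort("noise_variance must be positive")

  batch_count <- as.integer(batch_count)
  if (batch_count < 1L) abort("batch_count must be >= 1")
  batches <- paste0("batch", seq_len(batch_count))
  if (!is.data.frame(batch_additive)) {
    batch_additive <- tidyr::expand_grid(gene = genes, batch = batches) |>
      dplyr::mutate(gamma = rep_len(batch_additive, batch_count)[match(.data$batch, batches)])
  }
  if (!is.data.frame(batch_multiplicative)) {
    batch_multiplicative <- tidyr::expand_grid(gene = genes, batch = batches) |>
      dplyr::mutate(delta = rep_len(batch_multiplicative, batch_count)[match(.data$batch, batches)])
  }
  if (any(batch_multiplicative$delta <= 0)) abort("batch delta scales must be positive")

  if (!is.null(bimodal)) {
    stopifnot(all(c("genes", "weight", "separation") %in% names(bimodal)))
    if (!all(bimodal$genes %in% targets)) {
      abort("bimodal genes must be non-hub panel genes")
    }
    if (bimodal$weight <= 0 || bimodal$weight >= 1) {
      abort("bimodal weight must lie in (0, 1)")
    }
  }

  structure(
    list(
      genes = genes, hub = hub, stage_sizes = stage_sizes,
      stage_means = stage_means, hub_variance = hub_variance,
      planted_r2 = planted_r2, noise_variance = noise_variance,
      batch_count = batch_count, batches = batches,
      batch_additive = batch_additive,
      batch_multiplicative = batch_multiplicative,
      bimodal = bimodal, seed = as.integer(seed)
    ),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat("<coupling_spec>\n")
  cat("  genes:", length(x$genes), "| hub:", x$hub, "\n")
  cat("  stage sizes:",
      paste(names(x$stage_sizes), x$stage_sizes, sep = "=", collapse = ", "),
      "\n")
  cat("  batches:", x$batch_count, "| seed:", x$seed, "\n")
  invisible(x)
}

# Mean-zero residual draw: Gaussian, or a two-component normal mixture with
# the same variance for genes declared bimodal.
draw_residual <- function(n, var, bimodal_active, weight, separation) {
  if (!bimodal_active) {
    return(rnorm(n, 0, sqrt(var)))
  }
  between <- weight * (1 - weight) * separation^2
  if (between >= var) {
    abort("bimodal separation too large for the residual variance")
  }
  comp_sd <- sqrt(var - between)
  upper <- runif(n) < weight
  centers <- ifelse(upper, (1 - weight) * separation, -weight * separation)
  centers + rnorm(n, 0, comp_sd)
}

#' Simulate a stage-stratified expression study
#'
#' Per stage, hub samples are drawn from the spec's normal law; each target
#' equals its stage mean plus `beta * (hub - hub mean)` plus residual noise,
#' with `beta` from [coupling_slope()] so the planted R-squared holds in
#' expectation. Batch labels are assigned round-robin within stage (so stage
#' and batch are not confounded) and batch effects are applied in
#' location/scale form: the additive shift gamma is added, and the residual
#' deviation from the stage mean is scaled by `sqrt(delta)`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expression` (tibble, `gene_id` + sample columns) and
#'   `annotation` (tibble `sample_id`, `stage`, `batch`).
#' @export
#' @examples
#' spec <- synthetic_spec(stage_sizes = c(normal = 20, adenoma = 20, carcinoma = 30))
#' sim <- simulate_expression(spec)
#' dim(sim$expression)
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  set.seed(spec$seed)
  stages <- stage_levels()
  genes <- spec$genes
  targets <- setdiff(genes, spec$hub)

  means <- tidyr::pivot_wider(spec$stage_means, names_from = "stage",
                              values_from = "mean")
  mean_of <- function(gene, stage) {
    means[[stage]][match(gene, means$gene)]
  }
  r2_tab <- tidyr::pivot_wider(spec$planted_r2, names_from = "stage",
                               values_from = "r2")
  nv_tab <- tidyr::pivot_wider(spec$noise_variance, names_from = "stage",
                               values_from = "var")

  blocks <- list()
  ann <- list()
  for (stage in stages) {
    n <- spec$stage_sizes[[stage]]
    hub_mu <- mean_of(spec$hub, stage)
    hub_var <- spec$hub_variance[[stage]]
    hub_vals <- rnorm(n, hub_mu, sqrt(hub_var))
    m <- matrix(NA_real_, nrow = length(genes), ncol = n,
                dimnames = list(genes, NULL))
    m[spec$hub, ] <- hub_vals
    for (g in targets) {
      r2 <- r2_tab[[stage]][match(g, r2_tab$gene)]
      nv <- nv_tab[[stage]][match(g, nv_tab$gene)]
      beta <- coupling_slope(r2, hub_var, nv)
      bim <- !is.null(spec$bimodal) && g %in% spec$bimodal$genes
      eps <- draw_residual(n, nv, bim,
                           if (bim) spec$bimodal$weight else 0,
                           if (bim) spec$bimodal$separation else 0)
      m[g, ] <- mean_of(g, stage) + beta * (hub_vals - hub_mu) + eps
    }
    ids <- sprintf("%s_%03d", stage, seq_len(n))
    colnames(m) <- ids
    batch <- spec$batches[((seq_len(n) - 1L) %% spec$batch_count) + 1L]

    # location/scale batch effects around the stage mean
    stage_mu <- vapply(genes, mean_of, numeric(1), stage = stage)
    gam <- tidyr::pivot_wider(spec$batch_additive, names_from = "batch",
                              values_from = "gamma")
    del <- tidyr::pivot_wider(spec$batch_multiplicative, names_from = "batch",
                              values_from = "delta")
    for (b in unique(batch)) {
      idx <- which(batch == b)
      g_shift <- gam[[b]][match(genes, gam$gene)]
      d_scale <- del[[b]][match(genes, del$gene)]
      m[, idx] <- stage_mu + g_shift +
        sqrt(d_scale) * (m[, idx, drop = FALSE] - stage_mu)
    }
    blocks[[stage]] <- m
    ann[[stage]] <- tibble::tibble(sample_id = ids, stage = stage, batch = batch)
  }

  mat <- do.call(cbind, blocks)
  list(
    expression = expr_tibble(mat),
    annotation = dplyr::bind_rows(ann)
  )
}

#' Simulate a global-null expression study
#'
#' All genes i.i.d. normal with identical means across stages and zero
#' cross-gene coupling; used as the type-I-error harness for correlation,
#' ANOVA and FDR calibration.
#'
#' @param genes Gene identifiers.
#' @param stage_sizes Named samples per stage.
#' @param seed Integer seed.
#' @param mean,sd Shared normal law for every gene (log2 scale).
#' @return As [simulate_expression()].
#' @export
simulate_null_expression <- function(genes = panel_genes(),
                                     stage_sizes = c(normal = 100L,
                                                     adenoma = 100L,
                                                     carcinoma = 100L),
                                     seed = 1L, mean = 7, sd = 1) {
  stopifnot(setequal(names(stage_sizes), stage_levels()))
  set.seed(as.integer(seed))
  total <- sum(stage_sizes)
  m <- matrix(rnorm(length(genes) * total, mean, sd),
              nrow = length(genes), dimnames = list(genes, NULL))
  stage <- rep(stage_levels(), times = stage_sizes[stage_levels()])
  ids <- sprintf("%s_%03d", stage, unlist(lapply(stage_sizes[stage_levels()], seq_len)))
  colnames(m) <- ids
  list(
    expression = expr_tibble(m),
    annotation = tibble::tibble(sample_id = ids, stage = stage, batch = "batch1")
  )
}

#' Serialize / deserialize a synthetic spec as JSON
#'
#' @param spec A [synthetic_spec()].
#' @param path File path.
#' @return `read_spec_json()` returns a `coupling_spec`;
#'   `write_spec_json()` returns `path` invisibly.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "coupling_spec"))
  payload <- list(
    genes = spec$genes, hub = spec$hub,
    stage_sizes = as.list(spec$stage_sizes),
    stage_means = spec$stage_means,
    hub_variance = as.list(spec$hub_variance),
    planted_r2 = spec$planted_r2,
    noise_variance = spec$noise_variance,
    batch_count = spec$batch_count,
    batch_additive = spec$batch_additive,
    batch_multiplicative = spec$batch_multiplicative,
    bimodal = spec$bimodal,
    seed = spec$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(p$bimodal) == 0L) p$bimodal <- NULL
  synthetic_spec(
    genes = p$genes, hub = p$hub,
    stage_sizes = unlist(p$stage_sizes),
    stage_means = tibble::as_tibble(p$stage_means),
    hub_variance = unlist(p$hub_variance),
    planted_r2 = tibble::as_tibble(p$planted_r2),
    noise_variance = tibble::as_tibble(p$noise_variance),
    batch_count = p$batch_count,
    batch_additive = tibble::as_tibble(p$batch_additive),
    batch_multiplicative = tibble::as_tibble(p$batch_multiplicative),
    bimodal = p$bimodal,
    seed = p$seed
  )
}
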