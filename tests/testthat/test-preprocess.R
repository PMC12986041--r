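# Two batches with gene-specific batch effects centred on the requested
# per-batch gamma/delta (batch effects on arrays are gene-specific; the EB
# prior needs across-gene spread to be meaningful).
make_batch_data <- function(n_per_batch = 200, n_genes = 20, gamma = c(1, -1),
                            delta = c(1, 1), stage_diff = 0, seed = 1,
                            gamma_spread = 1, delta_spread = 0.2) {
  set.seed(seed)
  stages <- rep(c("normal", "carcinoma"), length.out = 2 * n_per_batch)
  batch <- rep(c("batch1", "batch2"), each = n_per_batch)
  ids <- sprintf("s%04d", seq_along(batch))
  m <- matrix(rnorm(n_genes * length(ids), 7, 1), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)), ids))
  gamma_g <- lapply(gamma, function(g) rnorm(n_genes, g, gamma_spread))
  delta_g <- lapply(delta, function(d) exp(rnorm(n_genes, log(d), delta_spread)))
  for (b in seq_along(gamma)) {
    idx <- batch == paste0("batch", b)
    m[, idx] <- 7 + gamma_g[[b]] + sqrt(delta_g[[b]]) * (m[, idx] - 7)
  }
  m[1, stages == "carcinoma"] <- m[1, stages == "carcinoma"] + stage_diff
  list(
    expression = expr_tibble(m),
    annotation = tibble::tibble(sample_id = ids, stage = stages,
                                batch = batch),
    gamma_g = gamma_g, delta_g = delta_g
  )
}

test_that("probe aggregation averages same-gene probes and drops ambiguous ones", {
  probe_expr <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    s1 = c(2, 4, 1, 5), s2 = c(4, 6, 2, 6)
  )
  probe_map <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbol = c("GENEA", "GENEA", "GENE1///GENE2", "GENEB")
  )
  out <- aggregate_probes(probe_expr, probe_map)
  m <- expr_matrix(out$expression)
  expect_equal(m["GENEA", ], c(s1 = 3, s2 = 5))
  expect_equal(m["GENEB", ], c(s1 = 5, s2 = 6))
  expect_false(any(c("GENE1", "GENE2") %in% rownames(m)))
  expect_equal(out$dropped_probes, "p3")
  expect_setequal(out$dropped_genes, c("GENE1", "GENE2"))
  # sample count and ordering conserved
  expect_equal(colnames(m), c("s1", "s2"))
  expect_error(
    aggregate_probes(probe_expr[1:2, ], probe_map[-1, ]),
    "does not cover"
  )
})

test_that("planted additive batch effects are removed within 0.05", {
  data <- make_batch_data(n_per_batch = 200, gamma = c(1, -1), seed = 31)
  res <- correct_batch_effects(data$expression, data$annotation)
  m <- expr_matrix(res$corrected)
  for (g in rownames(m)[-1]) {
    b1 <- mean(m[g, data$annotation$batch == "batch1"])
    b2 <- mean(m[g, data$annotation$batch == "batch2"])
    expect_lt(abs(b1 - b2), 0.05)
  }
  # raw gamma-hat estimates (relative to the batch-weighted grand mean)
  # track the planted gene-specific shifts
  centred <- (data$gamma_g[[1]] - data$gamma_g[[2]]) / 2
  expect_gt(cor(res$model$additive_batch[, "batch1"], centred), 0.98)
  expect_lt(cor(res$model$additive_batch[, "batch2"], centred), -0.98)
})

test_that("planted stage differences survive correction within 0.05", {
  data <- make_batch_data(n_per_batch = 200, gamma = c(0, 0),
                          gamma_spread = 0, delta_spread = 0,
                          stage_diff = 1, seed = 32)
  res <- correct_batch_effects(data$expression, data$annotation)
  m0 <- expr_matrix(data$expression)
  m <- expr_matrix(res$corrected)
  stage_diff <- function(mm) {
    mean(mm[1, data$annotation$stage == "carcinoma"]) -
      mean(mm[1, data$annotation$stage == "normal"])
  }
  expect_equal(stage_diff(m), stage_diff(m0), tolerance = 0.05)
  expect_equal(stage_diff(m), 1, tolerance = 0.2)
})

test_that("planted multiplicative effects equalize residual variances within 10%", {
  data <- make_batch_data(n_per_batch = 500, gamma = c(0, 0),
                          delta = c(4, 1), seed = 33)
  res <- correct_batch_effects(data$expression, data$annotation)
  m0 <- expr_matrix(data$expression)
  m <- expr_matrix(res$corrected)
  ratio <- function(mm, g) {
    var(mm[g, data$annotation$batch == "batch1"]) /
      var(mm[g, data$annotation$batch == "batch2"])
  }
  before <- vapply(rownames(m), ratio, numeric(1), mm = m0)
  after <- vapply(rownames(m), ratio, numeric(1), mm = m)
  expect_gt(mean(before), 3) # the planted four-fold spread is really there
  expect_lt(abs(mean(after) - 1), 0.1)
  expect_lt(max(abs(after - 1)), 3 * sqrt(2 / 500) * sqrt(2) * 3)
})

test_that("correction matches the reference empirical-Bayes implementation", {
  data <- make_batch_data(n_per_batch = 60, gamma = c(0.8, -0.8),
                          delta = c(2, 0.7), stage_diff = 0.6, seed = 34)
  res <- correct_batch_effects(data$expression, data$annotation)
  m <- expr_matrix(data$expression)
  stage <- factor(data$annotation$stage)
  ref <- sva::ComBat(dat = m, batch = data$annotation$batch,
                     mod = model.matrix(~stage))
  expect_lt(max(abs(expr_matrix(res$corrected) - ref)), 1e-3)
})

test_that("degenerate inputs are handled: single batch, zero-variance gene", {
  data <- make_batch_data(n_per_batch = 30, gamma = c(0.5, -0.5), seed = 35)
  one_batch <- data$annotation
  one_batch$batch <- "batch1"
  expect_warning(res <- correct_batch_effects(data$expression, one_batch),
                 "single batch")
  expect_identical(res$corrected, data$expression)

  m <- expr_matrix(data$expression)
  m["g1", ] <- 5
  res2 <- correct_batch_effects(expr_tibble(m), data$annotation)
  expect_equal(res2$model$flagged_genes, "g1")
  expect_equal(expr_matrix(res2$corrected)["g1", ], m["g1", ])
})

test_that("re-correcting corrected data is a near-identity", {
  data <- make_batch_data(n_per_batch = 200, gamma = c(1, -1),
                          delta = c(1.5, 0.8), seed = 36)
  once <- correct_batch_effects(data$expression, data$annotation)
  twice <- correct_batch_effects(once$corrected, data$annotation)
  d1 <- expr_matrix(once$corrected) - expr_matrix(data$expression)
  d2 <- expr_matrix(twice$corrected) - expr_matrix(once$corrected)
  # shrinkage leaves O(1/sqrt(n)) residual effects: the second pass must be
  # an order of magnitude smaller than the first, in both max and RMS norm
  expect_lt(max(abs(d2)), max(abs(d1)) / 10)
  expect_lt(sqrt(mean(d2^2)), sqrt(mean(d1^2)) / 10)
})

test_that("CV report flags constants and matches hand computation", {
  m <- rbind(flat = c(2, 2, 2), spread = c(1, 3, 2.5), wide = c(1, 3, 5))
  colnames(m) <- paste0("s", 1:3)
  rep <- qc_cv(expr_tibble(m))
  expect_true(rep$flagged[rep$gene == "flat"])
  expect_equal(rep$cv[rep$gene == "flat"], 0)
  two <- qc_cv(expr_tibble(rbind(g = c(1, 3),
                                 h = c(2, 5))[, , drop = FALSE] |>
                             (\(x) {colnames(x) <- c("a", "b"); x})()))
  expect_equal(two$cv[two$gene == "g"], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(round(two$cv[two$gene == "g"], 4), 0.7071)

  # the default synthetic study satisfies the CV > 0.2 property for all genes
  sim <- simulate_expression(synthetic_spec(seed = 6))
  expect_equal(sum(qc_cv(sim$expression)$flagged), 0L)
})

test_that("standardizer learns on train only and inverts exactly", {
  m <- rbind(g1 = c(1, 2, 3, 10), g2 = c(4, 8, 6, -2))
  colnames(m) <- c("a", "b", "c", "d")
  expr <- expr_tibble(m)
  std <- fit_standardizer(expr, c("a", "b", "c"))
  z <- expr_matrix(apply_standardizer(std, expr))
  expect_equal(z["g1", c("a", "b", "c")], c(a = -1, b = 0, c = 1))
  # train columns have mean 0, sd 1
  expect_lt(max(abs(rowMeans(z[, c("a", "b", "c")]))), 1e-10)
  expect_lt(max(abs(apply(z[, c("a", "b", "c")], 1, sd) - 1)), 1e-10)
  # a shifted test point keeps its shift in standardized units
  expect_equal(z["g1", "d"], (10 - 2) / 1)
  # two-pass brute-force oracle
  for (g in rownames(m)) {
    mu <- mean(m[g, 1:3]); s <- sd(m[g, 1:3])
    expect_equal(z[g, ], (m[g, ] - mu) / s, tolerance = 1e-12)
  }
  back <- expr_matrix(unstandardize(std, apply_standardizer(std, expr)))
  expect_lt(max(abs(back - m)), 1e-10)

  flat <- expr_tibble(rbind(gz = c(1, 1, 1))[, , drop = FALSE] |>
                        (\(x) {colnames(x) <- c("a", "b", "c"); x})())
  expect_error(fit_standardizer(flat), "gz")
})

test_that("silhouette diagnostic favours stage after correction", {
  spec <- synthetic_spec(
    stage_sizes = c(normal = 60, adenoma = 60, carcinoma = 60),
    batch_count = 2L, batch_additive = c(2.5, -2.5),
    batch_multiplicative = 1, seed = 14
  )
  sim <- simulate_expression(spec)
  before <- silhouette_diagnostic(sim$expression, sim$annotation)
  res <- correct_batch_effects(sim$expression, sim$annotation)
  after <- silhouette_diagnostic(res$corrected, sim$annotation)
  sil <- function(tbl, g) tbl$mean_silhouette[tbl$grouping == g]
  expect_gt(sil(before, "batch"), sil(after, "batch"))
  expect_gt(sil(after, "stage"), sil(after, "batch"))
})
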