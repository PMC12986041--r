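fake_records <- function(hub, targets, stage_means_r2, second_hub = NULL,
                         second_means = NULL) {
  # constructs a correlation table whose hub-target R2 values average to the
  # requested per-stage means (all targets share the stage value)
  rows <- list()
  for (i in seq_along(stage_levels())) {
    s <- stage_levels()[i]
    for (t in targets) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_a = hub, gene_b = t, stage = s,
        r = sqrt(stage_means_r2[i]), r_squared = stage_means_r2[i],
        p_value = 0.01, q_value = 0.02, n = 100
      )
    }
    if (!is.null(second_hub)) {
      for (t in targets) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_a = second_hub, gene_b = t, stage = s,
          r = sqrt(second_means[i]), r_squared = second_means[i],
          p_value = 0.5, q_value = 0.6, n = 100
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("pearson_r reproduces hand-computed and boundary cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 2:3), "3 samples")
})

test_that("pearson_r agrees with the sum oracle and cor.test", {
  set.seed(101)
  for (i in 1:5) {
    x <- rnorm(50)
    y <- 0.3 * x + rnorm(50)
    res <- pearson_r(x, y)
    expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("BH step-up matches hand computation and stays monotone", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:5) {
    p <- runif(40)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_equal(order(q[order(p)]), seq_along(p)) # q ranks follow p ranks
  }
})

test_that("stage tables cover all 91 pairs and are sample-order invariant", {
  sim <- simulate_expression(synthetic_spec(
    stage_sizes = c(normal = 30, adenoma = 30, carcinoma = 30),
    batch_count = 1L, batch_additive = 0, batch_multiplicative = 1,
    seed = 19
  ))
  tab <- stage_correlation_table(sim$expression, sim$annotation)
  expect_equal(nrow(tab), 3L * 91L)
  expect_true(all(tab$q_value >= tab$p_value))
  expect_lt(max(abs(tab$r_squared - tab$r^2)), 1e-12)

  perm <- sample(seq_len(nrow(sim$annotation)))
  expr_perm <- sim$expression[, c(1, perm + 1)]
  ann_perm <- sim$annotation[perm, ]
  tab2 <- stage_correlation_table(expr_perm, ann_perm)
  expect_equal(tab, tab2, tolerance = 1e-12)

  short <- sim$annotation
  short$stage[short$stage == "normal"] <- "adenoma"
  expect_error(stage_correlation_table(sim$expression, short), "normal")
})

test_that("a uniquely planted strong pair attains the minimum q-value", {
  for (seed in 1:10) {
    spec <- synthetic_spec(
      genes = c("DDR2", "COL11A1", "MMP2", "FN1"),
      stage_sizes = c(normal = 30, adenoma = 30, carcinoma = 352),
      planted_r2 = tidyr::expand_grid(
        gene = c("COL11A1", "MMP2", "FN1"), stage = stage_levels()
      ) |>
        dplyr::mutate(r2 = ifelse(gene == "COL11A1" & stage == "carcinoma",
                                  0.549, 0.02)),
      batch_count = 1L, batch_additive = 0, batch_multiplicative = 1,
      seed = seed
    )
    sim <- simulate_expression(spec)
    tab <- stage_correlation_table(sim$expression, sim$annotation,
                                   stages = "carcinoma")
    top <- tab[which.min(tab$q_value), ]
    expect_equal(sort(c(top$gene_a, top$gene_b)), c("COL11A1", "DDR2"))
  }
})

test_that("hub summaries reproduce the printed fold and divergence ratios", {
  rec <- fake_records("DDR2", paste0("T", 1:12), c(0.147, 0.234, 0.380),
                      second_hub = "DDR1",
                      second_means = c(0.031, 0.021, 0.017))
  hs <- hub_coupling_summary(rec, "DDR2", paste0("T", 1:12))
  expect_equal(hs$mean_r2, c(0.147, 0.234, 0.380), tolerance = 1e-12)
  expect_equal(round(hs$overall_fold[1], 2), 2.59)
  expect_equal(round(hs$transition_fold[2], 2), 1.59)
  expect_equal(round(hs$transition_fold[3], 2), 1.62)

  div <- hub_divergence(rec, "DDR2", "DDR1")
  expect_equal(round(div$ratio[div$stage == "carcinoma"], 1), 22.4)
  expect_equal(round(div$ratio[div$stage == "normal"], 1), 4.7)

  zero <- fake_records("DDR2", paste0("T", 1:12), c(0, 0, 0))
  hz <- hub_coupling_summary(zero, "DDR2", paste0("T", 1:12))
  expect_equal(hz$mean_r2, c(0, 0, 0))
  expect_true(is.na(hz$overall_fold[1]))

  expect_error(hub_coupling_summary(rec, "DDR2", c("T1", "MISSING")),
               "MISSING")
})

test_that("trajectories derive deltas, folds and kinetic classes", {
  rec <- dplyr::bind_rows(
    tibble::tibble(gene_a = "DDR2", gene_b = "COL11A1",
                   stage = stage_levels(),
                   r_squared = c(0.006, 0.235, 0.549)),
    tibble::tibble(gene_a = "DDR2", gene_b = "COL5A2",
                   stage = stage_levels(),
                   r_squared = c(0.325, 0.384, 0.577)),
    tibble::tibble(gene_a = "A", gene_b = "B", stage = stage_levels(),
                   r_squared = c(0.2, 0.2, 0.2)),
    tibble::tibble(gene_a = "C", gene_b = "D", stage = stage_levels(),
                   r_squared = c(0.3, 0.25, 0.15)),
    tibble::tibble(gene_a = "E", gene_b = "F", stage = stage_levels(),
                   r_squared = c(0.0005, 0.1, 0.2))
  )
  t1 <- coupling_trajectory(rec, "DDR2", "COL11A1")
  expect_equal(t1$delta_overall, 0.543, tolerance = 1e-12)
  expect_equal(t1$kinetic_class, "de_novo")
  t2 <- coupling_trajectory(rec, "DDR2", "COL5A2")
  expect_equal(t2$kinetic_class, "progressive")
  t3 <- coupling_trajectory(rec, "A", "B")
  expect_equal(t3$delta_overall, 0)
  expect_equal(t3$kinetic_class, "flat")
  expect_equal(coupling_trajectory(rec, "C", "D")$kinetic_class, "declining")
  # ratio suppressed below the near-zero denominator floor
  t5 <- coupling_trajectory(rec, "E", "F")
  expect_true(is.na(t5$fold_normal_to_adenoma))
  expect_true(is.na(t5$fold_overall))
  expect_false(is.na(t5$delta_overall))

  all_t <- coupling_trajectories(rec)
  expect_equal(nrow(all_t), 5L)
  expect_lt(max(abs(all_t$delta_overall -
                      (all_t$delta_normal_to_adenoma +
                         all_t$delta_adenoma_to_carcinoma))), 1e-12)
})

test_that("average-linkage clustering on 1-|r| matches a brute-force oracle", {
  # perfectly correlated and anti-correlated pairs merge at height 0
  cm <- diag(1, 3)
  dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cm["A", "B"] <- cm["B", "A"] <- 1
  cm["A", "C"] <- cm["C", "A"] <- -1
  cm["B", "C"] <- cm["C", "B"] <- -1
  tree <- correlation_cluster(cm)
  expect_equal(max(tree$height), 0)

  set.seed(33)
  x <- matrix(rnorm(4 * 40), 4)
  rownames(x) <- c("G1", "G2", "G3", "G4")
  cm4 <- cor(t(x))
  tree4 <- correlation_cluster(cm4)
  oracle <- oracle_average_linkage_heights(1 - abs(cm4))
  expect_equal(sort(tree4$height), sort(oracle), tolerance = 1e-10)

  bad <- cm4
  bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(correlation_cluster(bad), "symmetric")

  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree4, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, rownames(x))
})

test_that("stage tables equal a naive double-loop oracle on random panels", {
  set.seed(55)
  m <- matrix(rnorm(14 * 50), 14,
              dimnames = list(panel_genes(), sprintf("s%02d", 1:50)))
  ann <- tibble::tibble(sample_id = colnames(m), stage = "carcinoma",
                        batch = "b1")
  # guard: stage_correlation_table requires >= 3 samples and full stages
  tab <- stage_correlation_table(expr_tibble(m), ann, stages = "carcinoma")
  worst <- 0
  for (i in seq_len(nrow(tab))) {
    o <- oracle_pearson(m[tab$gene_a[i], ], m[tab$gene_b[i], ])
    worst <- max(worst, abs(tab$r[i] - o))
  }
  expect_lt(worst, 1e-10)
})
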