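make_separable_data <- function(n_per_stage, gap_sd = 3, n_genes = 14,
                                seed = 1) {
  set.seed(seed)
  stages <- stage_levels()
  X <- NULL
  y <- NULL
  for (i in seq_along(stages)) {
    centre <- rep(0, n_genes)
    centre[1:4] <- (i - 1) * gap_sd
    block <- matrix(rnorm(n_per_stage * n_genes), n_per_stage, n_genes)
    block <- block + rep(centre, each = n_per_stage)
    X <- rbind(X, block)
    y <- c(y, rep(stages[i], n_per_stage))
  }
  colnames(X) <- paste0("g", seq_len(n_genes))
  list(x = scale(X), y = factor(y, levels = stages))
}

test_that("stratified split reproduces the 476/102/102 partition", {
  ann <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:680),
    stage = rep(stage_levels(), times = c(158, 170, 352))
  )
  sp <- stratified_split(ann, c(0.70, 0.15, 0.15), seed = 4)
  expect_equal(sum(sp$split == "train"), 476L)
  expect_equal(sum(sp$split == "validation"), 102L)
  expect_equal(sum(sp$split == "test"), 102L)
  expect_setequal(sp$sample_id, ann$sample_id)
  # per-stage proportions within one sample of target
  for (s in stage_levels()) {
    n_s <- sum(ann$stage == s)
    for (frac_i in 1:3) {
      got <- sum(sp$stage == s &
                   sp$split == c("train", "validation", "test")[frac_i])
      expect_lte(abs(got - n_s * c(0.70, 0.15, 0.15)[frac_i]), 1 + 1e-9)
    }
  }
  expect_identical(sp, stratified_split(ann, c(0.70, 0.15, 0.15), seed = 4))
  expect_false(identical(sp$split,
                         stratified_split(ann, seed = 5)$split))

  all_train <- stratified_split(ann, c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  expect_error(stratified_split(ann, c(0.6, 0.3, 0.3)), "sum to 1")
})

test_that("forward pass normalizes, saturates and guards tiny batches", {
  cfg <- classifier_config(input_dim = 5, seed = 2)
  set.seed(2)
  params <- stagecoupling:::init_network(cfg)
  X <- matrix(rnorm(40), 8, 5)
  fwd <- stagecoupling:::classifier_forward(params, X, cfg, mode = "eval")
  expect_equal(rowSums(fwd$probs), rep(1, 8), tolerance = 1e-9)
  expect_true(all(fwd$probs >= 0))
  expect_error(
    stagecoupling:::classifier_forward(params, X[1, , drop = FALSE], cfg,
                                       mode = "train"),
    "size 1"
  )

  # softmax of equal logits is uniform; large margins saturate at any shift
  sm <- stagecoupling:::softmax_rows
  expect_equal(sm(matrix(0, 1, 3))[1, ], rep(1 / 3, 3))
  for (L in c(-50, 0, 300)) {
    p <- sm(matrix(c(L, L - 20, L - 20), 1))
    expect_gt(p[1, 1], 0.9999)
  }
})

test_that("cross-entropy has its closed-form values", {
  perfect <- matrix(c(1, 0, 0), 1)
  expect_equal(cross_entropy(perfect, 1L), 0, tolerance = 1e-9)
  uniform <- matrix(1 / 3, 2, 3)
  expect_equal(cross_entropy(uniform, c(1L, 3L)), log(3), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cfg <- classifier_config(
    input_dim = 4, hidden_sizes = c(5, 4), dropout_rates = c(0, 0),
    classes = 3, l2_lambda = 0.01, use_dropout = FALSE, seed = 6
  )
  set.seed(6)
  params <- stagecoupling:::init_network(cfg)
  X <- matrix(rnorm(7 * 4), 7, 4)
  y <- sample(1:3, 7, replace = TRUE)

  loss_at <- function(p) {
    fwd <- stagecoupling:::classifier_forward(p, X, cfg, mode = "train")
    cross_entropy(fwd$probs, y) +
      cfg$l2_lambda * (sum(p$out$W^2) +
                         sum(vapply(p$layers, function(l) sum(l$W^2),
                                    numeric(1))))
  }
  fwd <- stagecoupling:::classifier_forward(params, X, cfg, mode = "train")
  grads <- stagecoupling:::classifier_backward(params, fwd, X, y, cfg)

  h <- 1e-5
  check_tensor <- function(getter, setter, g) {
    theta <- getter(params)
    idx <- seq_along(theta)
    for (i in idx) {
      pp <- params; th <- theta; th[i] <- theta[i] + h
      pp <- setter(pp, th)
      up <- loss_at(pp)
      pp <- params; th <- theta; th[i] <- theta[i] - h
      pp <- setter(pp, th)
      down <- loss_at(pp)
      fd <- (up - down) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
  for (l in 1:2) {
    for (nm in c("W", "b", "gamma", "beta")) {
      check_tensor(
        function(p) p$layers[[l]][[nm]],
        function(p, v) {
          dim(v) <- dim(p$layers[[l]][[nm]])
          p$layers[[l]][[nm]] <- v
          p
        },
        grads$layers[[l]][[nm]]
      )
    }
  }
  check_tensor(function(p) p$out$W,
               function(p, v) { dim(v) <- dim(p$out$W); p$out$W <- v; p },
               grads$out$W)
  check_tensor(function(p) p$out$b,
               function(p, v) { p$out$b <- v; p }, grads$out$b)
})

test_that("Adam with zero gradient leaves parameters unchanged", {
  cfg <- classifier_config(input_dim = 3, hidden_sizes = 4,
                           dropout_rates = 0, seed = 1)
  set.seed(1)
  params <- stagecoupling:::init_network(cfg)
  state <- stagecoupling:::init_adam_state(params)
  zero_grads <- list(
    layers = lapply(params$layers, function(ly) {
      list(W = ly$W * 0, b = ly$b * 0, gamma = ly$gamma * 0,
           beta = ly$beta * 0)
    }),
    out = list(W = params$out$W * 0, b = params$out$b * 0)
  )
  upd <- stagecoupling:::adam_update(params, zero_grads, state, t = 1,
                                     lr = 0.1, cfg)
  expect_identical(upd$params, params)
})

test_that("training is deterministic with batchnorm and dropout disabled", {
  data <- make_separable_data(30, gap_sd = 2, seed = 9)
  cfg <- classifier_config(use_batchnorm = FALSE, use_dropout = FALSE,
                           max_epochs = 10, seed = 5)
  m1 <- train_classifier(data$x, data$y, data$x, data$y, cfg)
  m2 <- train_classifier(data$x, data$y, data$x, data$y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("the network separates well-separated synthetic stages", {
  data <- make_separable_data(50, gap_sd = 3, seed = 12)
  # linear separability oracle on the same draw
  lda_fit <- MASS::lda(data$x, grouping = data$y)
  lda_acc <- mean(predict(lda_fit, data$x)$class == data$y)
  expect_gte(lda_acc, 0.95)

  val <- make_separable_data(40, gap_sd = 3, seed = 13)
  cfg <- classifier_config(max_epochs = 100, seed = 21)
  model <- train_classifier(data$x, data$y, val$x, val$y, cfg)
  expect_gte(model$best_val_accuracy, 0.95)
  expect_true(all(c("epoch", "train_loss", "val_accuracy",
                    "learning_rate") %in% names(model$history)))
})

test_that("checkpoint restores the best validation accuracy epoch", {
  data <- make_separable_data(40, gap_sd = 2.5, seed = 31)
  val <- make_separable_data(30, gap_sd = 2.5, seed = 32)
  cfg <- classifier_config(max_epochs = 60, seed = 33)
  model <- train_classifier(data$x, data$y, val$x, val$y, cfg)
  probs <- predict(model, val$x, type = "prob")
  acc <- mean(max.col(probs) == as.integer(val$y))
  expect_equal(acc, model$best_val_accuracy, tolerance = 1e-12)
  expect_equal(model$best_val_accuracy, max(model$history$val_accuracy))
})

test_that("evaluation metrics match their definitions and oracles", {
  # constant single-class predictor on a balanced set has accuracy 1/3
  cfg <- classifier_config(input_dim = 4, hidden_sizes = 5,
                           dropout_rates = 0, seed = 3)
  set.seed(3)
  params <- stagecoupling:::init_network(cfg)
  params$out$W[] <- 0
  params$out$b <- c(10, 0, 0)
  model <- structure(
    list(params = params, classes = stage_levels(), config = cfg,
         best_val_accuracy = NA, history = NULL),
    class = "coupling_classifier"
  )
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(stage_levels(), each = 10)
  met <- evaluate_classifier(model, x, y)
  expect_equal(met$accuracy, 1 / 3)
  expect_equal(unname(met$confusion[, "normal"]), rep(1, 3))
  expect_equal(met$per_class$recall[met$per_class$class == "normal"], 1)
  expect_equal(met$per_class$precision[met$per_class$class == "normal"],
               1 / 3)
  # row-normalized confusion rows sum to one
  expect_equal(unname(rowSums(met$confusion)), rep(1, 3), tolerance = 1e-9)
  # F1 is the harmonic mean of its precision and recall
  pc <- met$per_class[met$per_class$class == "normal", ]
  expect_equal(pc$f1, 2 * pc$precision * pc$recall / (pc$precision + pc$recall),
               tolerance = 1e-12)
})

test_that("trapezoidal AUC equals the all-pairs concordance count", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  auc <- auc_trapezoid(roc_points(scores, truth))
  expect_equal(auc, oracle_auc(scores, truth), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:5) {
    s <- round(runif(30), 2) # ties likely
    t <- runif(30) < 0.4
    if (!any(t) || all(t)) next
    expect_equal(auc_trapezoid(roc_points(s, t)), oracle_auc(s, t),
                 tolerance = 1e-12)
  }
  expect_error(roc_points(c(1, 0), c(TRUE, TRUE)), "positive and negative")
})

test_that("perfect predictions give perfect metrics", {
  data <- make_separable_data(25, gap_sd = 6, seed = 41)
  val <- make_separable_data(20, gap_sd = 6, seed = 42)
  cfg <- classifier_config(max_epochs = 60, seed = 43)
  model <- train_classifier(data$x, data$y, val$x, val$y, cfg)
  met <- evaluate_classifier(model, val$x, val$y)
  if (met$accuracy == 1) {
    expect_equal(unname(diag(met$confusion)), rep(1, 3))
    expect_true(all(met$per_class$f1 == 1))
  }
  expect_true(all(met$per_class$auc >= 0.99))
})

test_that("config invariants are enforced", {
  expect_error(classifier_config(split_fractions = c(0.5, 0.3, 0.3)),
               "sum to 1")
  expect_error(classifier_config(dropout_rates = c(0.3, 1, 0.2)),
               "dropout")
})
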