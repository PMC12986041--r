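#' Configuration of the feed-forward stage classifier
#'
#' Defaults follow the published architecture and optimizer settings: three
#' hidden layers (64, 32, 16) with batch normalization (epsilon 1e-5) and
#' dropout (0.3, 0.3, 0.2), softmax output over the three stages,
#' cross-entropy loss with L2 weight penalty 1e-5, Adam (alpha 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-8), mini-batches of 32, plateau
#' learning-rate halving on validation accuracy (patience 15), early stopping
#' (patience 30), and a 70/15/15 stratified split.
#'
#' @param input_dim Number of input features (genes).
#' @param hidden_sizes Hidden layer widths.
#' @param dropout_rates Per-hidden-layer dropout probabilities.
#' @param classes Number of output classes.
#' @param batchnorm_epsilon,learning_rate,adam_beta1,adam_beta2,adam_epsilon
#'   Numerical/optimizer constants.
#' @param l2_lambda L2 penalty coefficient on weight matrices (not biases or
#'   batchnorm parameters).
#' @param batch_size Mini-batch size; a trailing remainder batch is kept.
#' @param lr_factor,lr_patience Plateau scheduler: multiply the learning rate
#'   by `lr_factor` after `lr_patience` epochs without validation
#'   improvement.
#' @param early_stop_patience Stop after this many non-improving epochs.
#' @param max_epochs Upper bound on training epochs.
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @param use_batchnorm,use_dropout Toggles, mainly for gradient checking and
#'   determinism tests.
#' @param bn_momentum Running-statistics update momentum.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(input_dim = 14L,
                              hidden_sizes = c(64L, 32L, 16L),
                              dropout_rates = c(0.3, 0.3, 0.2),
                              classes = 3L,
                              batchnorm_epsilon = 1e-5,
                              learning_rate = 0.001,
                              adam_beta1 = 0.9,
                              adam_beta2 = 0.999,
                              adam_epsilon = 1e-8,
                              l2_lambda = 1e-5,
                              batch_size = 32L,
                              lr_factor = 0.5,
                              lr_patience = 15L,
                              early_stop_patience = 30L,
                              max_epochs = 300L,
                              split_fractions = c(0.70, 0.15, 0.15),
                              use_batchnorm = TRUE,
                              use_dropout = TRUE,
                              bn_momentum = 0.1,
                              seed = 1L) {
  stopifnot(length(hidden_sizes) == length(dropout_rates))
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    abort("split_fractions must sum to 1")
  }
  if (any(dropout_rates < 0 | dropout_rates >= 1)) {
    abort("dropout rates must lie in [0, 1)")
  }
  structure(
    list(
      input_dim = as.integer(input_dim),
      hidden_sizes = as.integer(hidden_sizes),
      dropout_rates = dropout_rates,
      classes = as.integer(classes),
      batchnorm_epsilon = batchnorm_epsilon,
      learning_rate = learning_rate,
      adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
      adam_epsilon = adam_epsilon,
      l2_lambda = l2_lambda,
      batch_size = as.integer(batch_size),
      lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
      early_stop_patience = as.integer(early_stop_patience),
      max_epochs = as.integer(max_epochs),
      split_fractions = split_fractions,
      use_batchnorm = isTRUE(use_batchnorm),
      use_dropout = isTRUE(use_dropout),
      bn_momentum = bn_momentum,
      seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

#' Stratified train/validation/test split
#'
#' Partitions samples so that each split's per-stage proportions stay within
#' one sample of the target fractions, with global split sizes fixed by
#' largest-remainder rounding of the totals (680 samples at 0.70/0.15/0.15
#' give 476/102/102). Deterministic given the seed.
#'
#' @param annotation Annotation tibble with `sample_id`, `stage`.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `stage`, `split`
#'   (`train`/`validation`/`test`).
#' @export
stratified_split <- function(annotation, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  stopifnot(all(c("sample_id", "stage") %in% names(annotation)))
  splits <- c("train", "validation", "test")
  stages <- unique(annotation$stage)
  n_total <- nrow(annotation)

  largest_remainder <- function(n, frac) {
    raw <- n * frac
    base <- floor(raw)
    extra <- round(n - sum(base))
    rem_order <- order(raw - base, decreasing = TRUE)
    base[rem_order[seq_len(extra)]] <- base[rem_order[seq_len(extra)]] + 1L
    base
  }
  global_target <- largest_remainder(n_total, fractions)

  # per-stage floors, then distribute stage leftovers by descending
  # fractional remainder subject to the global split targets
  quota <- matrix(0L, nrow = length(stages), ncol = 3L,
                  dimnames = list(stages, splits))
  rem <- quota * 0
  for (s in stages) {
    n_s <- sum(annotation$stage == s)
    raw <- n_s * fractions
    quota[s, ] <- floor(raw)
    rem[s, ] <- raw - floor(raw)
  }
  stage_need <- vapply(stages, function(s) {
    as.integer(sum(annotation$stage == s) - sum(quota[s, ]))
  }, integer(1))
  split_need <- global_target - colSums(quota)
  cells <- expand.grid(stage = stages, split = splits,
                       stringsAsFactors = FALSE)
  cells$rem <- rem[cbind(cells$stage, cells$split)]
  cells <- cells[order(-cells$rem, cells$stage, cells$split), ]
  while (sum(stage_need) > 0L) {
    assigned <- FALSE
    for (i in seq_len(nrow(cells))) {
      st <- cells$stage[i]; sp <- cells$split[i]
      if (stage_need[st] > 0L && split_need[sp] > 0L) {
        quota[st, sp] <- quota[st, sp] + 1L
        stage_need[st] <- stage_need[st] - 1L
        split_need[sp] <- split_need[sp] - 1L
        assigned <- TRUE
      }
    }
    if (!assigned) abort("internal error: infeasible split quotas")
  }

  set.seed(as.integer(seed))
  out <- purrr::map_dfr(stages, function(s) {
    ids <- annotation$sample_id[annotation$stage == s]
    ids <- sample(ids)
    assign <- rep(splits, times = quota[s, ])
    tibble::tibble(sample_id = ids, stage = s, split = assign)
  })
  out[match(annotation$sample_id, out$sample_id), ]
}

# ---- network internals -----------------------------------------------------

add_bias <- function(M, b) M + rep(b, each = nrow(M))

init_network <- function(config) {
  sizes <- c(config$input_dim, config$hidden_sizes)
  layers <- lapply(seq_along(config$hidden_sizes), function(l) {
    fan_in <- sizes[l]
    h <- sizes[l + 1]
    bound <- 1 / sqrt(fan_in)
    list(
      W = matrix(runif(fan_in * h, -bound, bound), fan_in, h),
      b = runif(h, -bound, bound),
      gamma = rep(1, h), beta = rep(0, h),
      run_mean = rep(0, h), run_var = rep(1, h)
    )
  })
  fan_in <- sizes[length(sizes)]
  bound <- 1 / sqrt(fan_in)
  out <- list(
    W = matrix(runif(fan_in * config$classes, -bound, bound),
               fan_in, config$classes),
    b = runif(config$classes, -bound, bound)
  )
  list(layers = layers, out = out)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass of the stage classifier
#'
#' Train mode uses mini-batch statistics for batch normalization and samples
#' dropout masks; eval mode uses running statistics and no dropout.
#'
#' @param params Network parameters (weights, biases, batchnorm state).
#' @param X Numeric matrix, samples x features.
#' @param config A [classifier_config()].
#' @param mode `"train"` or `"eval"`.
#' @return List: `probs` (samples x classes), `cache` (per-layer
#'   intermediates for backprop), and in train mode updated running
#'   statistics in `params`.
#' @keywords internal
classifier_forward <- function(params, X, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), ncol(X) == config$input_dim)
  n <- nrow(X)
  if (mode == "train" && n < 2L) {
    abort("batch statistics undefined for a train-mode batch of size 1")
  }
  eps <- config$batchnorm_epsilon
  H <- X
  cache <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    Z <- add_bias(H %*% ly$W, ly$b)
    if (config$use_batchnorm) {
      if (mode == "train") {
        mu <- colMeans(Z)
        v <- pmax(colMeans(Z^2) - mu^2, 0)
        mom <- config$bn_momentum
        params$layers[[l]]$run_mean <- (1 - mom) * ly$run_mean + mom * mu
        params$layers[[l]]$run_var <- (1 - mom) * ly$run_var +
          mom * v * n / (n - 1)
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + eps)
      Xhat <- (Z - rep(mu, each = n)) * rep(inv_sd, each = n)
      A <- add_bias(Xhat * rep(ly$gamma, each = n), ly$beta)
    } else {
      mu <- NULL; v <- NULL; inv_sd <- NULL; Xhat <- NULL
      A <- Z
    }
    R <- pmax(A, 0)
    if (config$use_dropout && mode == "train" && config$dropout_rates[l] > 0) {
      p <- config$dropout_rates[l]
      mask <- matrix(
        (runif(length(R)) >= p) / (1 - p), nrow(R), ncol(R)
      )
      Hout <- R * mask
    } else {
      mask <- NULL
      Hout <- R
    }
    cache[[l]] <- list(H_in = H, Z = Z, mu = mu, v = v, inv_sd = inv_sd,
                       Xhat = Xhat, A = A, mask = mask)
    H <- Hout
  }
  logits <- add_bias(H %*% params$out$W, params$out$b)
  probs <- softmax_rows(logits)
  list(probs = probs, cache = cache, H_last = H, params = params)
}

#' Cross-entropy loss
#'
#' Mean over samples of `-log p(true class)`, with probabilities clamped at
#' 1e-12 to keep the loss finite at degenerate predictions.
#'
#' @param probs Samples x classes probability matrix.
#' @param y Integer class indices (1-based) per sample.
#' @return Scalar loss.
#' @export
cross_entropy <- function(probs, y) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  -mean(log(p))
}

# Backward pass: returns gradients of cross-entropy + L2 w.r.t. all
# trainable parameters, given the forward cache.
classifier_backward <- function(params, fwd, X, y, config) {
  n <- nrow(X)
  eps <- config$batchnorm_epsilon
  Y <- matrix(0, n, config$classes)
  Y[cbind(seq_len(n), y)] <- 1
  dlogits <- (fwd$probs - Y) / n

  grads <- list(layers = vector("list", length(params$layers)), out = NULL)
  grads$out <- list(
    W = crossprod(fwd$H_last, dlogits) + 2 * config$l2_lambda * params$out$W,
    b = colSums(dlogits)
  )
  dH <- dlogits %*% t(params$out$W)

  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    cc <- fwd$cache[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dR <- dH
    dA <- dR * (cc$A > 0)
    if (config$use_batchnorm) {
      dgamma <- colSums(dA * cc$Xhat)
      dbeta <- colSums(dA)
      dXhat <- dA * rep(ly$gamma, each = n)
      Zc <- cc$Z - rep(cc$mu, each = n)
      dv <- colSums(dXhat * Zc) * (-0.5) * (cc$v + eps)^(-1.5)
      dmu <- colSums(dXhat) * (-cc$inv_sd) + dv * (-2) * colMeans(Zc)
      dZ <- dXhat * rep(cc$inv_sd, each = n) +
        rep(dv, each = n) * 2 * Zc / n +
        rep(dmu, each = n) / n
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- dA
    }
    grads$layers[[l]] <- list(
      W = crossprod(cc$H_in, dZ) + 2 * config$l2_lambda * ly$W,
      b = colSums(dZ),
      gamma = dgamma, beta = dbeta
    )
    dH <- dZ %*% t(ly$W)
  }
  grads
}

# One Adam update over the parameter tree. `state` mirrors the tree with m/v
# moments; `t` is the global step (after increment).
adam_update <- function(params, grads, state, t, lr, config) {
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- config$adam_epsilon
  upd <- function(theta, g, st) {
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    m_hat <- st$m / (1 - b1^t)
    v_hat <- st$v / (1 - b2^t)
    theta <- theta - lr * m_hat / (sqrt(v_hat) + eps)
    list(theta = theta, st = st)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads$layers[[l]][[nm]]
      if (is.null(g)) next
      r <- upd(params$layers[[l]][[nm]], g, state$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- r$theta
      state$layers[[l]][[nm]] <- r$st
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(params$out[[nm]], grads$out[[nm]], state$out[[nm]])
    params$out[[nm]] <- r$theta
    state$out[[nm]] <- r$st
  }
  list(params = params, state = state)
}

init_adam_state <- function(params) {
  zero_like <- function(x) list(m = x * 0, v = x * 0)
  list(
    layers = lapply(params$layers, function(ly) {
      list(W = zero_like(ly$W), b = zero_like(ly$b),
           gamma = zero_like(ly$gamma), beta = zero_like(ly$beta))
    }),
    out = list(W = zero_like(params$out$W), b = zero_like(params$out$b))
  )
}

#' Train the feed-forward stage classifier
#'
#' Mini-batch training with per-epoch shuffling, Adam, L2 weight penalty,
#' plateau learning-rate scheduling and early stopping on validation
#' accuracy, restoring the checkpoint with the highest validation accuracy.
#'
#' @param x_train,x_val Numeric matrices (samples x features), already
#'   standardized with training statistics.
#' @param y_train,y_val Factors (or vectors coercible to factor with shared
#'   levels) of stage labels.
#' @param config A [classifier_config()].
#' @return A `coupling_classifier`: best-checkpoint parameters, class
#'   levels, config, and a per-epoch `history` tibble (train loss,
#'   validation accuracy, learning rate).
#' @export
train_classifier <- function(x_train, y_train, x_val, y_val,
                             config = classifier_config()) {
  y_train <- as.factor(y_train)
  y_val <- factor(y_val, levels = levels(y_train))
  stopifnot(nlevels(y_train) == config$classes,
            ncol(x_train) == config$input_dim)
  yi_train <- as.integer(y_train)
  yi_val <- as.integer(y_val)

  set.seed(config$seed)
  params <- init_network(config)
  state <- init_adam_state(params)
  lr <- config$learning_rate
  t_step <- 0L
  n <- nrow(x_train)

  best_acc <- -Inf
  best_params <- params
  since_improve <- 0L
  since_lr_improve <- 0L
  history <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(n)
    starts <- seq(1, n, by = config$batch_size)
    batches <- lapply(starts, function(s) {
      idx[s:min(s + config$batch_size - 1L, n)]
    })
    # fold a trailing singleton into the previous batch
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) == 1L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    epoch_loss <- 0
    for (b in batches) {
      Xb <- x_train[b, , drop = FALSE]
      yb <- yi_train[b]
      fwd <- classifier_forward(params, Xb, config, mode = "train")
      params <- fwd$params # running stats updated
      loss <- cross_entropy(fwd$probs, yb) +
        config$l2_lambda * (sum(params$out$W^2) +
                              sum(vapply(params$layers,
                                         function(l) sum(l$W^2), numeric(1))))
      if (!is.finite(loss)) abort("non-finite training loss; aborting")
      grads <- classifier_backward(params, fwd, Xb, yb, config)
      t_step <- t_step + 1L
      upd <- adam_update(params, grads, state, t_step, lr, config)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + loss * length(b)
    }
    epoch_loss <- epoch_loss / n

    val_probs <- classifier_forward(params, x_val, config, mode = "eval")$probs
    val_acc <- mean(max.col(val_probs) == yi_val)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = epoch_loss,
      val_accuracy = val_acc, learning_rate = lr
    )

    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_params <- params
      since_improve <- 0L
      since_lr_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_lr_improve <- since_lr_improve + 1L
    }
    if (since_lr_improve >= config$lr_patience) {
      lr <- lr * config$lr_factor
      since_lr_improve <- 0L
    }
    if (since_improve >= config$early_stop_patience) break
  }

  structure(
    list(
      params = best_params,
      classes = levels(y_train),
      config = config,
      best_val_accuracy = best_acc,
      history = dplyr::bind_rows(history)
    ),
    class = "coupling_classifier"
  )
}

#' @export
print.coupling_classifier <- function(x, ...) {
  cat("<coupling_classifier>",
      paste(x$config$input_dim, paste(x$config$hidden_sizes, collapse = "-"),
            x$config$classes, sep = "-"),
      "| best val accuracy:", sprintf("%.4f", x$best_val_accuracy),
      "|", nrow(x$history), "epochs\n")
  invisible(x)
}

#' Predict stage probabilities or labels
#'
#' Inference uses running batchnorm statistics and no dropout.
#'
#' @param object A trained `coupling_classifier`.
#' @param newdata Numeric matrix (samples x features), standardized with the
#'   training statistics.
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @export
predict.coupling_classifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- classifier_forward(object$params, newdata, object$config,
                              mode = "eval")$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

# Gradient of one class's predicted probability with respect to the inputs,
# in eval mode (running statistics, no dropout). Returns samples x features.
classifier_input_gradient <- function(model, X, class_index) {
  config <- model$config
  params <- model$params
  fwd <- classifier_forward(params, X, config, mode = "eval")
  p <- fwd$probs
  n <- nrow(X)
  # d p_c / d logits = p_c * (1[c] - p)
  dlogits <- p * (-p[, class_index])
  dlogits[, class_index] <- dlogits[, class_index] + p[, class_index]
  dH <- dlogits %*% t(params$out$W)
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    cc <- fwd$cache[[l]]
    dA <- dH * (cc$A > 0)
    if (config$use_batchnorm) {
      scale <- ly$gamma / sqrt(ly$run_var + config$batchnorm_epsilon)
      dZ <- dA * rep(scale, each = n)
    } else {
      dZ <- dA
    }
    dH <- dZ %*% t(ly$W)
  }
  dH
}
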