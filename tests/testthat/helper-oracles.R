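# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Pearson r from the raw cross-product sums, written long-hand.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0
  dx2 <- 0
  dy2 <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    dx2 <- dx2 + (x[k] - mx)^2
    dy2 <- dy2 + (y[k] - my)^2
  }
  unname(num / sqrt(dx2 * dy2))
}

# Exhaustive average-linkage agglomeration over a distance matrix: cluster
# distances recomputed each step as the mean over all cross pairs of the
# ORIGINAL distances. Returns the merge heights in order.
oracle_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Studentized-range upper-tail probability by direct double numeric
# integration (k groups, df error degrees of freedom).
oracle_tukey_p <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) {
        stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      }
      k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  dens <- function(s) {
    # density of sqrt(chi2_df / df)
    exp((df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2 + log(2))
  }
  cdf <- stats::integrate(function(s) dens(s) * inner(s), 0, Inf,
                          rel.tol = 1e-9)$value
  1 - cdf
}

# Exact Shapley values by full coalition enumeration (single baseline b):
# f evaluated with out-of-coalition features replaced by the baseline.
oracle_shapley <- function(f, x, b) {
  n <- length(x)
  phi <- numeric(n)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  for (j in seq_len(n)) {
    for (r in seq_len(nrow(subsets))) {
      S <- unlist(subsets[r, ])
      if (S[j]) next
      size <- sum(S)
      w <- factorial(size) * factorial(n - size - 1) / factorial(n)
      x_with <- ifelse(S, x, b)
      x_with[j] <- x[j]
      x_without <- ifelse(S, x, b)
      phi[j] <- phi[j] + w * (f(x_with) - f(x_without))
    }
  }
  phi
}

# All-pairs concordance AUC (Mann-Whitney; ties count one half).
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# A hand-built small classifier (no batchnorm) with fixed weights, for
# attribution tests.
make_tiny_classifier <- function(W1, b1, W2, b2, classes) {
  config <- classifier_config(
    input_dim = nrow(W1), hidden_sizes = ncol(W1),
    dropout_rates = 0, classes = length(classes),
    use_batchnorm = FALSE, use_dropout = FALSE
  )
  params <- list(
    layers = list(list(W = W1, b = b1, gamma = rep(1, ncol(W1)),
                       beta = rep(0, ncol(W1)),
                       run_mean = rep(0, ncol(W1)),
                       run_var = rep(1, ncol(W1)))),
    out = list(W = W2, b = b2)
  )
  structure(list(params = params, classes = classes, config = config,
                 best_val_accuracy = NA_real_, history = NULL),
            class = "coupling_classifier")
}

# Two-gene spec with a planted hub-target trajectory and no batch effects.
two_gene_spec <- function(r2_by_stage, n_by_stage, seed,
                          target = "COL11A1") {
  synthetic_spec(
    genes = c("DDR2", target),
    stage_sizes = n_by_stage,
    planted_r2 = tibble::tibble(
      gene = target,
      stage = stage_levels(),
      r2 = r2_by_stage
    ),
    batch_count = 1L,
    batch_additive = 0,
    batch_multiplicative = 1,
    seed = seed
  )
}
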