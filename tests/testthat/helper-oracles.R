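# Independent oracles: literal, loop-based transcriptions of the formulas,
# deliberately written without reusing any package internals, so tests can
# compare the implementation against a second route.

# Entropy-weight composite scores, step by step.
entropy_weight_oracle <- function(X) {
  m <- nrow(X)
  n <- ncol(X)
  Z <- matrix(0, m, n)
  for (j in 1:n) {
    mx <- max(X[, j]); mn <- min(X[, j])
    if (mx > mn) for (i in 1:m) Z[i, j] <- (X[i, j] - mn) / (mx - mn)
  }
  Q <- matrix(0, m, n)
  for (j in 1:n) {
    s <- sum(Z[, j])
    for (i in 1:m) Q[i, j] <- if (s > 0) Z[i, j] / s else 1 / m
  }
  E <- numeric(n)
  for (j in 1:n) {
    acc <- 0
    for (i in 1:m) if (Q[i, j] > 0) acc <- acc + Q[i, j] * log(Q[i, j])
    E[j] <- -acc / log(m)
  }
  d <- 1 - E
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
  S <- numeric(m)
  for (i in 1:m) S[i] <- sum(w * Z[i, ])
  list(Z = Z, Q = Q, E = E, w = w, S = S)
}

# Per-row statistical features by direct evaluation.
feature_oracle <- function(p) {
  t(apply(p, 1, function(r) {
    mu <- sum(r) / 4
    c(max(r), min(r), mu, sqrt(sum((r - mu)^2) / 4))
  }))
}

# Five metrics from a confusion matrix by literal one-vs-rest counting.
metrics_oracle <- function(cm) {
  total <- sum(cm)
  k <- nrow(cm)
  acc <- sum(diag(cm)) / total
  prec <- rec <- f1 <- numeric(k)
  for (c in 1:k) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  pe <- 0
  for (c in 1:k) pe <- pe + sum(cm[c, ]) * sum(cm[, c])
  pe <- pe / total^2
  c(accuracy = acc, precision = mean(prec), recall = mean(rec),
    f1 = mean(f1), kappa = (acc - pe) / (1 - pe))
}

# Hard decision-tree lookup with the same cuts/leaf scores as a dndt_fit:
# per feature, the bin is found by explicit comparison against the sorted
# cut points; the leaf index follows the Kronecker ordering (first feature
# slowest); the class is the argmax of that leaf's scores, ensemble-summed.
hard_tree_oracle <- function(fit, x) {
  nb <- fit$config$tree_depth + 1
  n <- nrow(x)
  votes <- matrix(0, n, length(fit$levels))
  for (t in seq_along(fit$beta)) {
    beta <- fit$beta[[t]]
    subset <- fit$subsets[t, ] + 1
    m <- length(subset)
    for (i in seq_len(n)) {
      leaf <- 0
      for (d in seq_len(m)) {
        cuts <- sort(beta[d, ])
        bin <- sum(x[i, subset[d]] > cuts) # 0-based bin by comparison
        leaf <- leaf * nb + bin
      }
      scores <- fit$leaf[[t]][leaf + 1, ]
      votes[i, ] <- votes[i, ] + exp(scores - max(scores)) / sum(exp(scores - max(scores)))
    }
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

# TRUE where a sample sits farther than eps from every cut of every tree
# that bins it (hard/soft agreement is only claimed off the boundaries).
off_boundary <- function(fit, x, eps = 1e-2) {
  ok <- rep(TRUE, nrow(x))
  for (t in seq_along(fit$beta)) {
    beta <- fit$beta[[t]]
    subset <- fit$subsets[t, ] + 1
    for (d in seq_along(subset)) {
      for (cut in beta[d, ]) {
        ok <- ok & (abs(x[, subset[d]] - cut) > eps)
      }
    }
  }
  ok
}
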