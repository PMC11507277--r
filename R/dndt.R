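#' Soft binning of a scalar feature
#'
#' Maps a value `x` to a probability vector over `n + 1` bins defined by `n`
#' cut points `beta`: `softmax((w * x + b) / tau)` with the constant slope
#' vector `w = (1, 2, ..., n + 1)` and bias `b = (0, -beta1, -(beta1 + beta2),
#' ...)`. As `tau -> 0` the output approaches the one-hot indicator of the
#' interval containing `x`; larger `tau` softens the assignment.
#'
#' @param x numeric scalar (or vector, binned element-wise into rows).
#' @param cut_points numeric vector of cut points (sorted internally).
#' @param tau positive temperature.
#' @return For scalar `x` a simplex vector of length `length(cut_points)+1`;
#'   for vector `x` a matrix with one simplex row per element.
#' @export
soft_bin <- function(x, cut_points, tau = 0.1) {
  if (!is.numeric(tau) || tau <= 0) {
    stop("parameter error: tau must be positive", call. = FALSE)
  }
  beta <- sort(as.numeric(cut_points))
  nb <- length(beta) + 1
  w <- seq_len(nb)
  b <- c(0, -cumsum(beta))
  logits <- (outer(as.numeric(x), w) + matrix(b, length(x), nb, byrow = TRUE)) / tau
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  out <- e / rowSums(e)
  if (length(x) == 1) drop(out) else out
}

#' Kronecker-product leaf routing
#'
#' Combines per-feature bin vectors into a leaf-probability vector
#' `z = f1 (x) f2 (x) ... (x) fD` (first factor varies slowest). Each input
#' being a simplex, `z` is a simplex over the `prod(lengths)` leaves; in the
#' hard-binning limit it is the one-hot indicator of the reached leaf.
#'
#' @param bin_list list of per-feature simplex vectors.
#' @return Numeric leaf-probability vector.
#' @export
route_leaves <- function(bin_list) {
  Reduce(function(a, b) as.numeric(kronecker(a, b)), bin_list)
}

#' DNDT ensemble configuration
#'
#' Defaults are the tuned optima for this task: 7 trees, 1 cut point per
#' feature (`tree_depth`), learning rate 0.0025, batch size 16. Each tree
#' bins a random subset of `max_features_per_tree` of the 8 features (a full
#' Kronecker product over all 8 would allocate 2^8 leaves); tree outputs are
#' averaged. Temperature `tau` is fixed during training unless `tau_end` is
#' given, in which case it decays geometrically per epoch.
#'
#' @param num_trees number of trees in the ensemble.
#' @param tree_depth cut points per feature.
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size.
#' @param max_features_per_tree features drawn per tree (without replacement).
#' @param epochs training epochs.
#' @param tau training temperature; `tau_end` optional decay target.
#' @param tau_end optional final temperature for geometric decay.
#' @param seed integer seed controlling subsets, initialization and batches.
#' @return A `dndt_config` list.
#' @export
dndt_config <- function(num_trees = 7, tree_depth = 1, learning_rate = 0.0025,
                        batch_size = 16, max_features_per_tree = 4,
                        epochs = 200, tau = 0.1, tau_end = NULL, seed = 0L) {
  stopifnot(num_trees >= 1, tree_depth >= 1, batch_size >= 1,
            max_features_per_tree >= 1, epochs >= 1, tau > 0)
  structure(list(num_trees = as.integer(num_trees),
                 tree_depth = as.integer(tree_depth),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_features_per_tree = as.integer(max_features_per_tree),
                 epochs = as.integer(epochs),
                 tau = tau, tau_end = tau_end, seed = as.integer(seed)),
            class = "dndt_config")
}

#' Fit a deep neural decision tree ensemble
#'
#' Trains cut points and leaf class scores jointly by minibatch SGD on the
#' cross-entropy of the ensemble-averaged class distribution. Cut points are
#' initialized at the per-feature training quantiles and leaf scores at
#' small Gaussian noise; both are free parameters thereafter (cut points are
#' canonicalized by sorting at evaluation time). Deterministic given the
#' config seed.
#'
#' @param x numeric matrix or data frame of features.
#' @param y factor (or character) class labels, at least 2 classes.
#' @param config a [dndt_config()].
#' @return A `dndt_fit` object with elements `beta` (per-tree cut-point
#'   matrices), `leaf` (per-tree leaf-score matrices), `subsets`, `loss`
#'   (per-epoch mean training loss) and `levels`.
#' @export
fit_dndt <- function(x, y, config = dndt_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) {
    stop("degenerate target: need at least 2 classes", call. = FALSE)
  }
  n <- nrow(x)
  d <- ncol(x)
  m <- min(config$max_features_per_tree, d)
  nb <- config$tree_depth + 1
  L <- nb^m
  yi <- as.integer(y) - 1L

  state <- with_seed(config$seed, {
    subsets <- t(vapply(seq_len(config$num_trees),
                        function(t) sort(sample.int(d, m)) - 1L,
                        integer(m)))
    beta_init <- lapply(seq_len(config$num_trees), function(t) {
      bm <- matrix(0, m, config$tree_depth)
      for (dd in seq_len(m)) {
        col <- subsets[t, dd] + 1L
        probs <- seq_len(config$tree_depth) / nb
        bm[dd, ] <- as.numeric(stats::quantile(x[, col], probs, names = FALSE))
      }
      bm
    })
    leaf_init <- lapply(seq_len(config$num_trees), function(t) {
      matrix(stats::rnorm(L * nlevels(y), sd = 0.01), L, nlevels(y))
    })
    order_mat <- t(vapply(seq_len(config$epochs),
                          function(e) sample.int(n) - 1L, integer(n)))
    list(subsets = subsets, beta_init = beta_init, leaf_init = leaf_init,
         order_mat = order_mat)
  })

  tau_sched <- if (is.null(config$tau_end)) {
    rep(config$tau, config$epochs)
  } else {
    config$tau * (config$tau_end / config$tau)^
      (seq(0, 1, length.out = config$epochs))
  }

  res <- dndt_fit_cpp(x, yi, state$subsets, config$tree_depth, nlevels(y),
                      tau_sched, config$learning_rate, config$batch_size,
                      state$order_mat, state$beta_init, state$leaf_init)
  if (res$diverged_epoch > 0) {
    stop("divergence error: non-finite training loss at epoch ",
         res$diverged_epoch, call. = FALSE)
  }
  structure(list(beta = res$beta, leaf = res$leaf, subsets = state$subsets,
                 loss = as.numeric(res$loss), levels = levels(y),
                 tau = tau_sched[length(tau_sched)], config = config),
            class = "dndt_fit")
}

#' Class probabilities from a fitted DNDT ensemble
#'
#' Per tree, the leaf-routing vector is matrix-multiplied with the leaf
#' scores and softmaxed; the ensemble output is the mean over trees. Cut
#' points are sorted per feature before evaluation (the monotone
#' canonicalization of the binning). With `tau` near 0 this reproduces a
#' hard decision tree lookup.
#'
#' @param object a `dndt_fit`.
#' @param newdata feature matrix or data frame.
#' @param type `"prob"` for the class-probability matrix, `"class"` for hard
#'   labels (argmax, first-level tie-break).
#' @param tau optional evaluation temperature (defaults to the training
#'   value).
#' @param ... unused.
#' @export
predict.dndt_fit <- function(object, newdata, type = c("prob", "class"),
                             tau = NULL, ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  tau <- tau %||% object$tau
  beta_sorted <- lapply(object$beta, function(bm) {
    s <- apply(bm, 1, sort) # rows come back as columns; vector if one cut
    if (is.matrix(s)) t(s) else matrix(s, ncol = 1)
  })
  p <- dndt_predict_cpp(x, object$subsets, object$config$tree_depth,
                        length(object$levels), tau, beta_sorted, object$leaf)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

#' Fitted cut points of a DNDT ensemble
#'
#' The interpretability surface of the model: for each tree, the sorted cut
#' points of every feature it bins, as plain numbers.
#'
#' @param fit a `dndt_fit`.
#' @return List (one element per tree) of named lists mapping feature index
#'   to its sorted cut points.
#' @export
dndt_cut_points <- function(fit) {
  lapply(seq_along(fit$beta), function(t) {
    bm <- fit$beta[[t]]
    stats::setNames(
      lapply(seq_len(nrow(bm)), function(d) sort(bm[d, ])),
      paste0("feature_", fit$subsets[t, ] + 1L)
    )
  })
}
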