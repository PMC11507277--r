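# Entropy-weight composite scoring: objective weighting of the five
# evaluation metrics by the dispersion of their normalized distributions
# across models, and selection of the top-k base learners.

#' Entropy-weight composite scores of a model-by-metric matrix
#'
#' Given a matrix `X` of benefit criteria (rows = models, columns = metrics,
#' larger is better), computes, per column: min--max normalized values
#' `z = (x - min) / (max - min)` (a constant column is all-zero and receives
#' weight 0), proportions `q = z / sum(z)` (uniform for an all-zero column),
#' Shannon entropy `E = -(1/ln m) * sum(q ln q)` with the `0 ln 0 = 0`
#' convention, divergences `d = 1 - E`, weights `w = d / sum(d)` (uniform if
#' every column is constant), and finally the composite score of each model,
#' `S_i = sum_j w_j z_ij`. Models are then ranked by `S`.
#'
#' @param x numeric matrix or data frame, at least 2 rows; row names are the
#'   model names, column names the metric names.
#' @return A `score_matrix` list: `X`, `Z`, `Q`, `entropy`, `weights`,
#'   `scores` (named, in input row order).
#' @export
composite_scores <- function(x) {
  if (is.data.frame(x)) {
    if ("model" %in% names(x)) {
      rn <- x$model
      x <- as.matrix(x[setdiff(names(x), "model")])
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.numeric(x)) stop("validation error: non-numeric entries", call. = FALSE)
  if (nrow(x) < 2) {
    stop("degenerate-matrix error: need at least 2 models", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("validation error: non-finite entries in the metric matrix",
         call. = FALSE)
  }
  m <- nrow(x)
  n <- ncol(x)
  z <- matrix(0, m, n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    rng <- max(x[, j]) - min(x[, j])
    if (rng > 0) z[, j] <- (x[, j] - min(x[, j])) / rng
  }
  q <- matrix(0, m, n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    s <- sum(z[, j])
    q[, j] <- if (s > 0) z[, j] / s else rep(1 / m, m)
  }
  entropy <- apply(q, 2, function(qc) {
    qc <- qc[qc > 0]
    -sum(qc * log(qc)) / log(m)
  })
  d <- 1 - entropy
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
  names(w) <- colnames(x)
  scores <- as.numeric(z %*% w)
  names(scores) <- rownames(x)
  structure(list(X = x, Z = z, Q = q, entropy = entropy, weights = w,
                 scores = scores),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix>", nrow(x$X), "models,", ncol(x$X), "metrics\n")
  cat("weights:\n")
  print(round(x$weights, 4))
  cat("composite scores (ranked):\n")
  print(round(sort(x$scores, decreasing = TRUE), 4))
  invisible(x)
}

#' Select the top-k models by composite score
#'
#' @param scores a `score_matrix` from [composite_scores()] (or a named
#'   numeric vector of scores).
#' @param k number of models to select.
#' @return Character vector of `k` model names, by descending score; exact
#'   ties are broken by the row order of the input matrix, which is the
#'   package's canonical model order.
#' @export
select_top_k <- function(scores, k = 3) {
  s <- if (inherits(scores, "score_matrix")) scores$scores else scores
  if (k > length(s)) {
    stop("selection error: k exceeds the number of models", call. = FALSE)
  }
  names(s)[order(-s)][seq_len(k)] # order() is stable: ties keep input order
}

#' Evaluate candidates over repeated random splits
#'
#' For repeat `r` (with split seed `seed_base + r`) the labeled data are
#' split 80/20 with stratification, every candidate is fitted on the
#' training part and scored on the test part, and the per-repeat metric
#' tables are averaged entry-wise. Failed models are dropped from the
#' average and reported.
#'
#' @param specs list of [estimator_spec()]s.
#' @param data labeled posture dataset or feature table.
#' @param n_repeats number of repeated splits (default 10).
#' @param test_fraction held-out fraction per split.
#' @param seed_base split seed offset; repeat `r` uses `seed_base + r`.
#' @param average metric averaging mode.
#' @return List with `mean_metrics` (model x metric data frame), `repeats`
#'   (per-repeat metric tables), `errors` (named character).
#' @export
evaluate_candidates <- function(specs, data, n_repeats = 10,
                                test_fraction = 0.2, seed_base = 0L,
                                average = "macro") {
  stopifnot(n_repeats >= 1)
  features <- if (all(feature_cols() %in% names(data))) data else
    extract_features(data)
  repeats <- vector("list", n_repeats)
  errors <- character(0)
  for (r in seq_len(n_repeats)) {
    sp <- split_dataset(features, test_fraction = test_fraction,
                        stratified = TRUE, seed = seed_base + r)
    res <- fit_predict_all(specs, sp$train, sp$test, average = average)
    repeats[[r]] <- res$metrics
    errors <- c(errors, res$errors)
  }
  all_models <- unique(unlist(lapply(repeats, function(m) m$model)))
  mean_rows <- lapply(all_models, function(nm) {
    rows <- do.call(rbind, lapply(repeats, function(m) {
      m[m$model == nm, metric_cols(), drop = FALSE]
    }))
    colMeans(rows)
  })
  mean_metrics <- cbind(data.frame(model = all_models),
                        as.data.frame(do.call(rbind, mean_rows)))
  rownames(mean_metrics) <- NULL
  list(mean_metrics = mean_metrics, repeats = repeats, errors = errors)
}
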