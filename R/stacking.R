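# Two-layer stacking: out-of-fold base-model class probabilities become the
# meta-features for a multinomial logistic meta-learner.

#' Stratified fold assignment
#'
#' Assigns each sample a fold id in `1..k`, stratified by class so every
#' training fold (the complement of each fold) contains all classes.
#'
#' @param y label factor.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids.
#' @export
make_stratified_folds <- function(y, k = 5, seed = 0L) {
  stopifnot(k >= 2)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      members <- which(y == lv)
      folds[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  })
  for (kk in seq_len(k)) {
    train_classes <- unique(y[folds != kk])
    if (length(train_classes) < nlevels(y)) {
      missing_lv <- setdiff(levels(y), as.character(train_classes))
      stop("folding error: class '", missing_lv[1],
           "' missing from the training folds of fold ", kk, call. = FALSE)
    }
  }
  folds
}

#' Meta-learner specification
#'
#' Multinomial logistic regression with L2 regularization of strength
#' `C = 10`, realized as a ridge-penalized multinomial fit with
#' `lambda = 1 / (C * N)` (the exact correspondence between the sum-loss
#' C parameterization and a mean-loss ridge penalty).
#'
#' @param C inverse regularization strength.
#' @param penalty only `"l2"` is supported.
#' @return A `meta_learner_spec`.
#' @export
meta_learner_spec <- function(C = 10, penalty = "l2") {
  stopifnot(C > 0, identical(penalty, "l2"))
  structure(list(C = C, penalty = penalty), class = "meta_learner_spec")
}

#' Stacking configuration
#'
#' @param base_specs ordered list of base-model [estimator_spec()]s (order
#'   fixes the meta-feature column blocks).
#' @param n_folds folds for out-of-fold meta-features (default 5).
#' @param meta a [meta_learner_spec()].
#' @param meta_features `"prob"` (class probabilities, default) or
#'   `"labels"` (one-hot hard labels).
#' @param seed integer seed (fold assignment).
#' @return A `stacking_config`.
#' @export
stacking_config <- function(base_specs, n_folds = 5,
                            meta = meta_learner_spec(),
                            meta_features = c("prob", "labels"), seed = 0L) {
  stopifnot(length(base_specs) >= 1, n_folds >= 2)
  meta_features <- match.arg(meta_features)
  nm <- names(base_specs) %||% vapply(base_specs, function(s) s$name, "")
  names(base_specs) <- nm
  structure(list(base_specs = base_specs, n_folds = as.integer(n_folds),
                 meta = meta, meta_features = meta_features,
                 seed = as.integer(seed)),
            class = "stacking_config")
}

one_hot_rows <- function(p) {
  h <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  h[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))] <- 1
  h
}

#' Out-of-fold meta-features
#'
#' For every base model: the training block `Tr` holds, for each training
#' sample, the class probabilities predicted by the fold model whose
#' training folds exclude that sample (spliced fold by fold); the test block
#' `Te` holds the predictions of the same base model refit on the full
#' training set. Columns are ordered base model x class code.
#'
#' @param config a [stacking_config()].
#' @param train labeled training data (posture dataset or feature table).
#' @param test optional test data (features only needed).
#' @return List: `Tr` (N_train x models*classes), `Te` (or `NULL`),
#'   `fold_id`, `columns` (data frame of model/class per column),
#'   `full_fits` (base models refit on the full training set).
#' @export
build_meta_features <- function(config, train, test = NULL) {
  stopifnot(inherits(config, "stacking_config"))
  xtr <- feature_matrix(train)
  ytr <- train$label
  folds <- make_stratified_folds(ytr, config$n_folds, config$seed)
  n_class <- length(posture_levels())
  n_models <- length(config$base_specs)
  tr <- matrix(NA_real_, nrow(xtr), n_models * n_class)
  col_info <- data.frame(
    model = rep(names(config$base_specs), each = n_class),
    class = rep(posture_levels(), times = n_models)
  )
  colnames(tr) <- paste(col_info$model, col_info$class, sep = ".")
  for (j in seq_len(n_models)) {
    spec <- config$base_specs[[j]]
    block <- (j - 1) * n_class + seq_len(n_class)
    for (k in seq_len(config$n_folds)) {
      in_fold <- folds == k
      est <- fit_estimator(spec, xtr[!in_fold, , drop = FALSE], ytr[!in_fold])
      p <- predict(est, xtr[in_fold, , drop = FALSE], type = "prob")
      tr[in_fold, block] <- p[, posture_levels(), drop = FALSE]
    }
  }
  full_fits <- lapply(config$base_specs, function(spec) {
    fit_estimator(spec, xtr, ytr)
  })
  te <- NULL
  if (!is.null(test)) {
    xte <- feature_matrix(test)
    te <- do.call(cbind, lapply(full_fits, function(est) {
      predict(est, xte, type = "prob")[, posture_levels(), drop = FALSE]
    }))
    colnames(te) <- colnames(tr)
  }
  if (config$meta_features == "labels") {
    for (j in seq_len(n_models)) {
      block <- (j - 1) * n_class + seq_len(n_class)
      tr[, block] <- one_hot_rows(tr[, block, drop = FALSE])
      if (!is.null(te)) te[, block] <- one_hot_rows(te[, block, drop = FALSE])
    }
  }
  list(Tr = tr, Te = te, fold_id = folds, columns = col_info,
       full_fits = full_fits)
}

fit_meta_learner <- function(meta, tr, y) {
  n <- nrow(tr)
  lambda <- 1 / (meta$C * n)
  fit <- glmnet::glmnet(tr, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  list(fit = fit, lambda = lambda)
}

predict_meta_learner <- function(ml, newx) {
  p <- predict(ml$fit, newx = newx, s = ml$lambda, type = "response")
  p <- p[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p[, posture_levels(), drop = FALSE]
}

#' Fit the stacking ensemble
#'
#' Builds out-of-fold meta-features on the training data, fits the
#' multinomial logistic meta-learner on them, and retains full-train refits
#' of every base model for inference.
#'
#' @param config a [stacking_config()].
#' @param train labeled training data.
#' @return A `fitted_stack`.
#' @export
fit_stack <- function(config, train) {
  mf <- build_meta_features(config, train)
  ml <- fit_meta_learner(config$meta, mf$Tr, train$label)
  structure(list(config = config, meta = ml, base_fits = mf$full_fits,
                 meta_columns = mf$columns, fold_id = mf$fold_id),
            class = "fitted_stack")
}

#' Predict with a fitted stack
#'
#' Test samples pass through every (full-train) base model; the
#' concatenated class-probability blocks are fed to the meta-learner.
#'
#' @param object a `fitted_stack`.
#' @param newdata features (posture dataset, feature table or matrix).
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.fitted_stack <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(object$meta)) stop("state error: stack is not fitted",
                                 call. = FALSE)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  te <- do.call(cbind, lapply(object$base_fits, function(est) {
    predict(est, x, type = "prob")[, posture_levels(), drop = FALSE]
  }))
  if (object$config$meta_features == "labels") {
    n_class <- length(posture_levels())
    for (j in seq_along(object$base_fits)) {
      block <- (j - 1) * n_class + seq_len(n_class)
      te[, block] <- one_hot_rows(te[, block, drop = FALSE])
    }
  }
  colnames(te) <- paste(object$meta_columns$model, object$meta_columns$class,
                        sep = ".")
  p <- predict_meta_learner(object$meta, te)
  if (type == "prob") return(p)
  factor(posture_levels()[max.col(p, ties.method = "first")],
         levels = posture_levels())
}
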