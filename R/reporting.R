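# Feature-importance aggregation across base models and model-comparison
# reports with improvement ranges.

#' Permutation importance of one fitted model
#'
#' Accuracy drop after shuffling one feature column at a time, averaged over
#' `n_permutations` shuffles. The identity baseline uses the unpermuted
#' accuracy, so a feature the model ignores scores 0.
#'
#' @param est fitted estimator (anything with a `predict(..., type="class")`
#'   method over the 8 features).
#' @param features labeled feature table or posture dataset.
#' @param n_permutations shuffles per feature.
#' @param seed integer seed.
#' @return Named numeric vector over [feature_cols()] (raw drops, may be
#'   negative).
#' @export
permutation_importance <- function(est, features, n_permutations = 20,
                                   seed = 0L) {
  x <- feature_matrix(features)
  y <- as.character(features$label)
  base_acc <- mean(as.character(predict(est, x, type = "class")) == y)
  with_seed(seed, {
    drops <- vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_permutations), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base_acc - mean(as.character(predict(est, xp, type = "class")) == y)
      }, numeric(1)))
    }, numeric(1))
    stats::setNames(drops, colnames(x))
  })
}

# Split-gain importance of a fitted xgboost backend, mapped onto the 8
# canonical features (features never used by a split get 0).
xgboost_gain_importance <- function(est) {
  imp <- xgboost::xgb.importance(model = est$fitted)
  out <- stats::setNames(rep(0, length(feature_cols())), feature_cols())
  out[imp$Feature] <- imp$Gain
  out
}

#' Normalized feature-importance table across base models
#'
#' Tree-boosting models contribute their internal split-gain importances;
#' every other model is scored by permutation importance (negative drops
#' clipped to 0). Each model row is normalized to sum to 1; a row with no
#' informative feature is flagged degenerate and replaced by a uniform row
#' with a warning. An `average` row (the arithmetic mean of the model rows)
#' is appended.
#'
#' @param fits named list of fitted estimators (names are the model names).
#' @param features labeled validation data (feature table or dataset).
#' @param n_permutations shuffles per feature for permutation importance.
#' @param seed integer seed.
#' @return Data frame: one row per model plus `average`, columns
#'   [feature_cols()]; every row sums to 1.
#' @export
feature_importance <- function(fits, features, n_permutations = 20,
                               seed = 0L) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    est <- fits[[nm]]
    raw <- if (inherits(est, "posture_estimator") &&
               est$spec$name == "xgboost") {
      xgboost_gain_importance(est)
    } else {
      pmax(permutation_importance(est, features, n_permutations, seed), 0)
    }
    normalize_importance_row(raw, nm)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(fits)
  tab <- rbind(tab, average = colMeans(tab))
  as.data.frame(tab)
}

normalize_importance_row <- function(raw, name) {
  s <- sum(raw)
  if (s <= 0) {
    warning("degenerate importance row for model '", name,
            "' (no informative feature); substituting uniform", call. = FALSE)
    return(rep(1 / length(raw), length(raw)))
  }
  raw / s
}

#' Improvement ranges of the stacking model over competitors
#'
#' For each requested metric, the minimum and maximum of
#' `stacking value - competitor value`, in percentage points (values on the
#' \[0,1\] metric scale are multiplied by 100). Display values are rounded
#' to 2 decimals; the full-precision numbers are kept alongside.
#'
#' @param metric_table data frame with a `model` column and metric columns;
#'   must contain the stacking row.
#' @param stacking_model name of the stacking row (default `"stacking"`).
#' @param metrics metric columns to range over.
#' @return List: `improvements` (competitor x metric data frame of
#'   percentage-point differences) and `ranges` (per metric: `min`, `max`,
#'   rounded `min_display`, `max_display`).
#' @export
comparison_report <- function(metric_table, stacking_model = "stacking",
                              metrics = c("accuracy", "f1", "kappa")) {
  stopifnot(is.data.frame(metric_table), "model" %in% names(metric_table))
  missing_m <- setdiff(metrics, names(metric_table))
  if (length(missing_m) > 0) {
    stop("schema error: missing metric column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (!(stacking_model %in% metric_table$model)) {
    stop("schema error: stacking row '", stacking_model, "' not present",
         call. = FALSE)
  }
  stack_row <- metric_table[metric_table$model == stacking_model, , drop = FALSE]
  comp <- metric_table[metric_table$model != stacking_model, , drop = FALSE]
  if (nrow(comp) == 0) comp <- stack_row # self-comparison: ranges are (0, 0)
  improvements <- data.frame(model = comp$model)
  for (mt in metrics) {
    improvements[[mt]] <- 100 * (stack_row[[mt]] - comp[[mt]])
  }
  ranges <- lapply(metrics, function(mt) {
    v <- improvements[[mt]]
    list(min = min(v), max = max(v),
         min_display = round(min(v), 2), max_display = round(max(v), 2))
  })
  names(ranges) <- metrics
  list(improvements = improvements, ranges = ranges)
}

#' Bundled worked-example tables
#'
#' Small reference tables shipped with the package and used by the worked
#' examples and regression tests: `candidate_metrics` (five evaluation
#' metrics for the seven candidate models on the four-posture task),
#' `ensemble_comparison` (accuracy/F1/kappa of the stacking model and five
#' competitor ensembles) and `importance` (normalized per-model feature
#' contributions of the three selected base models).
#'
#' @param name table name.
#' @return Data frame.
#' @export
example_table <- function(name = c("candidate_metrics",
                                   "ensemble_comparison", "importance")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_example.csv"),
                      package = "posturestack", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
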