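# End-to-end orchestration: data -> features -> (optional tuning) ->
# candidate evaluation -> entropy-weight selection -> stacking -> reports,
# with every artifact and seed recorded in a manifest.

#' Pipeline run configuration
#'
#' @param data a labeled [posture_dataset()], or `NULL` to generate
#'   synthetic data from `generator`.
#' @param generator list of [generate_postures()] arguments (used when
#'   `data` is `NULL`).
#' @param candidates character vector of candidate model names (default all
#'   implemented candidates; the optional `tabnet` slot is excluded).
#' @param k number of base models to select (default 3).
#' @param n_repeats repeated splits for candidate evaluation.
#' @param test_fraction held-out fraction.
#' @param tune run Bayesian optimization per candidate before evaluation
#'   (off by default; the tuned defaults are used).
#' @param tune_iterations budget per model when tuning.
#' @param n_folds stacking folds.
#' @param seed global seed; stage seeds derive from it.
#' @return A `run_config`.
#' @export
run_config <- function(data = NULL,
                       generator = list(n_per_class = 200, separability = 0.2),
                       candidates = c("xgboost", "rf", "svm", "elm", "mlp",
                                      "dndt"),
                       k = 3, n_repeats = 10, test_fraction = 0.2,
                       tune = FALSE, tune_iterations = 30, n_folds = 5,
                       seed = 0L) {
  structure(list(data = data, generator = generator, candidates = candidates,
                 k = k, n_repeats = n_repeats, test_fraction = test_fraction,
                 tune = tune, tune_iterations = tune_iterations,
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full posture-recognition pipeline
#'
#' Stages, in order: dataset snapshot; feature table; per-candidate metric
#' matrix averaged over `n_repeats` stratified splits; entropy-weight
#' composite scores and top-`k` selection; stacking fit on one final split;
#' test metrics and confusion matrix; feature-importance and comparison
#' reports. Each stage writes a CSV/JSON artifact to `out_dir` and the
#' manifest records seeds, resolved hyperparameters and file checksums.
#' Rerunning with the same config reproduces all numeric artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`data`,
#'   `candidate_metrics`, `scores`, `selected`, `stack`, `test_metrics`,
#'   `importance`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("posturestack_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  stage_file <- function(name) file.path(out_dir, name)
  log_stage <- function(stage, file, extra = NULL) {
    entry <- c(list(file = basename(file),
                    md5 = unname(tools::md5sum(file))), extra)
    manifest$stages[[stage]] <<- entry
  }

  data <- config$data %||% do.call(generate_postures,
                                   c(config$generator, list(seed = config$seed)))
  write_posture_csv(data, stage_file("dataset.csv"))
  log_stage("dataset", stage_file("dataset.csv"),
            list(n = nrow(data), provenance = attr(data, "provenance")))

  features <- extract_features(data)
  utils::write.csv(features, stage_file("features.csv"), row.names = FALSE)
  log_stage("features", stage_file("features.csv"))

  specs <- lapply(config$candidates, function(nm) {
    hp <- if (config$tune) {
      optimize_hyperparams(nm, features,
                           n_iterations = config$tune_iterations,
                           seed = config$seed)$best_params
    } else {
      list()
    }
    estimator_spec(nm, hyperparameters = hp, seed = config$seed)
  })
  names(specs) <- config$candidates

  ev <- evaluate_candidates(specs, features, n_repeats = config$n_repeats,
                            test_fraction = config$test_fraction,
                            seed_base = config$seed)
  utils::write.csv(ev$mean_metrics, stage_file("candidate_metrics.csv"),
                   row.names = FALSE)
  log_stage("candidate_metrics", stage_file("candidate_metrics.csv"),
            list(n_repeats = config$n_repeats,
                 hyperparameters = lapply(specs, hyperparameters)))

  sm <- composite_scores(ev$mean_metrics)
  selected <- select_top_k(sm, k = min(config$k, length(sm$scores)))
  utils::write.csv(data.frame(model = names(sm$scores),
                              score = unname(sm$scores)),
                   stage_file("composite_scores.csv"), row.names = FALSE)
  jsonlite::write_json(selected, stage_file("selected_models.json"))
  log_stage("selection", stage_file("composite_scores.csv"),
            list(selected = selected, weights = as.list(sm$weights)))

  sp <- split_dataset(features, test_fraction = config$test_fraction,
                      stratified = TRUE, seed = config$seed)
  stack_cfg <- stacking_config(specs[selected], n_folds = config$n_folds,
                               seed = config$seed)
  stack <- fit_stack(stack_cfg, sp$train)
  pred <- predict(stack, sp$test, type = "class")
  prob <- predict(stack, sp$test, type = "prob")
  cm <- confusion_matrix(sp$test$label, pred)
  test_metrics <- score_confusion(cm)
  utils::write.csv(as.data.frame(unclass(cm)),
                   stage_file("confusion_matrix.csv"))
  utils::write.csv(round(confusion_proportions(cm), 4),
                   stage_file("confusion_proportions.csv"))
  utils::write.csv(data.frame(metric = names(test_metrics),
                              value = unname(test_metrics)),
                   stage_file("stack_test_metrics.csv"), row.names = FALSE)
  pred_out <- data.frame(row_id = seq_len(nrow(sp$test)), label = pred)
  colnames(prob) <- paste0("p_", colnames(prob))
  utils::write.csv(cbind(pred_out, prob), stage_file("stack_predictions.csv"),
                   row.names = FALSE)
  log_stage("stack", stage_file("stack_test_metrics.csv"),
            list(base_models = selected, n_folds = config$n_folds,
                 test_metrics = as.list(test_metrics)))

  imp <- feature_importance(stack$base_fits, sp$test, seed = config$seed)
  utils::write.csv(cbind(model = rownames(imp), imp),
                   stage_file("feature_importance.csv"), row.names = FALSE)
  log_stage("importance", stage_file("feature_importance.csv"))

  comp_in <- rbind(ev$mean_metrics[ev$mean_metrics$model %in% selected,
                                   c("model", "accuracy", "f1", "kappa")],
                   data.frame(model = "stacking",
                              accuracy = test_metrics[["accuracy"]],
                              f1 = test_metrics[["f1"]],
                              kappa = test_metrics[["kappa"]]))
  comp <- comparison_report(comp_in)
  utils::write.csv(comp$improvements, stage_file("improvements.csv"),
                   row.names = FALSE)
  log_stage("comparison", stage_file("improvements.csv"),
            list(ranges = comp$ranges))

  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data, candidate_metrics = ev$mean_metrics,
                 scores = sm, selected = selected, stack = stack,
                 test_metrics = test_metrics, importance = imp,
                 comparison = comp, manifest = manifest, out_dir = out_dir))
}
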