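# Shared estimator contract for the candidate classifiers. Each candidate is
# configured by an estimator_spec whose hyperparameter names and admissible
# ranges mirror the tuned search table shipped with the package; models that
# are sensitive to feature scale (svm, elm, mlp) get a standardizer fitted on
# training rows only.

#' Candidate model names
#' @return Character vector of the seven candidate identifiers.
#' @export
model_names <- function() c("xgboost", "rf", "svm", "elm", "mlp", "dndt", "tabnet")

#' Hyperparameter scopes of the candidate models
#'
#' The admissible domain of every tunable hyperparameter, per model: a
#' continuous interval, an integer range, or a categorical set. These are
#' both the validation ranges for [estimator_spec()] and the default search
#' spaces for [optimize_hyperparams()].
#'
#' @param name model name; `NULL` returns all.
#' @return Named list of dimension descriptors.
#' @export
hyperparameter_scopes <- function(name = NULL) {
  scopes <- list(
    xgboost = list(
      learning_rate = dim_real("learning_rate", 0.001, 0.5),
      max_depth = dim_int("max_depth", 1, 10),
      n_estimators = dim_int("n_estimators", 50, 500)
    ),
    svm = list(
      C = dim_real("C", 0.1, 10),
      Gamma = dim_real("Gamma", 0.001, 1),
      kernel = dim_cat("kernel", c("linear", "poly", "rbf"))
    ),
    rf = list(
      max_depth = dim_int("max_depth", 1, 20),
      min_samples_leaf = dim_int("min_samples_leaf", 1, 5),
      min_samples_split = dim_int("min_samples_split", 2, 10),
      n_estimators = dim_int("n_estimators", 50, 300)
    ),
    elm = list(
      n_neurons = dim_int("n_neurons", 100, 500),
      activation_func = dim_cat("activation_func", c("sigm", "tanh"))
    ),
    mlp = list(
      activation = dim_cat("activation", c("relu", "tanh")),
      alpha = dim_real("alpha", 0.0001, 0.01),
      solver = dim_cat("solver", c("adam", "sgd"))
    ),
    tabnet = list(
      dim_num_decision_steps = dim_int("dim_num_decision_steps", 3, 15),
      dim_relaxation_factor = dim_int("dim_relaxation_factor", 1, 5),
      dim_sparsity_coefficient = dim_real("dim_sparsity_coefficient", 1e-5, 1e-1)
    ),
    dndt = list(
      num_trees = dim_int("num_trees", 1, 10),
      tree_depth = dim_int("tree_depth", 1, 10),
      learning_rate = dim_real("learning_rate", 0.0001, 0.01),
      batch_size = dim_cat("batch_size", c(16, 32, 64, 128))
    )
  )
  if (is.null(name)) scopes else scopes[[match.arg(name, model_names())]]
}

#' Tuned default hyperparameters
#'
#' The per-model optima found by Bayesian optimization on the four-airbag
#' posture task; used whenever tuning is disabled.
#'
#' @param name model name.
#' @return Named list of hyperparameter values.
#' @export
default_hyperparameters <- function(name) {
  switch(match.arg(name, model_names()),
    xgboost = list(learning_rate = 0.169, max_depth = 5L, n_estimators = 300L),
    svm = list(C = 4.729, Gamma = 0.467, kernel = "rbf"),
    rf = list(max_depth = 7L, min_samples_leaf = 3L, min_samples_split = 5L,
              n_estimators = 269L),
    elm = list(n_neurons = 215L, activation_func = "tanh"),
    mlp = list(activation = "relu", alpha = 0.0084, solver = "adam"),
    tabnet = list(dim_num_decision_steps = 9L, dim_relaxation_factor = 1L,
                  dim_sparsity_coefficient = 1.256e-5),
    dndt = list(num_trees = 7L, tree_depth = 1L, learning_rate = 0.0025,
                batch_size = 16L)
  )
}

# Documented extra knobs accepted beyond the tuned table.
extra_params <- function(name) {
  switch(name,
    dndt = c("max_features_per_tree", "epochs", "tau", "tau_end"),
    mlp = c("hidden_units", "maxit"),
    elm = c("ridge"),
    character(0)
  )
}

scaling_models <- function() c("svm", "elm", "mlp")

check_in_scope <- function(name, param, value) {
  scope <- hyperparameter_scopes(name)[[param]]
  ok <- switch(scope$type,
    real = is.numeric(value) && value >= scope$lower && value <= scope$upper,
    int = is.numeric(value) && value == round(value) &&
      value >= scope$lower && value <= scope$upper,
    cat = value %in% scope$values
  )
  if (!ok) {
    dom <- if (scope$type == "cat") {
      paste0("{", paste(scope$values, collapse = ", "), "}")
    } else {
      sprintf("(%s, %s)", format(scope$lower), format(scope$upper))
    }
    stop(sprintf("range error: %s = %s outside documented scope %s for model %s",
                 param, format(value), dom, name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Specify a candidate estimator
#'
#' Creates a validated specification for one of the candidate models.
#' Hyperparameters default to the tuned optima; any value supplied is
#' checked against [hyperparameter_scopes()] and an out-of-scope value is a
#' range error citing the documented domain. Models sensitive to feature
#' scale (`svm`, `elm`, `mlp`) automatically compose a standardizer fitted
#' on training rows only.
#'
#' @param name one of [model_names()].
#' @param hyperparameters named list overriding the tuned defaults.
#' @param seed integer seed for any model randomness.
#' @return An `estimator_spec`.
#' @export
estimator_spec <- function(name, hyperparameters = list(), seed = 0L) {
  name <- match.arg(name, model_names())
  hp <- default_hyperparameters(name)
  known <- c(names(hyperparameter_scopes(name)), extra_params(name))
  for (p in names(hyperparameters)) {
    if (!(p %in% known)) {
      stop(sprintf("unknown hyperparameter '%s' for model %s", p, name),
           call. = FALSE)
    }
    if (p %in% names(hyperparameter_scopes(name))) {
      check_in_scope(name, p, hyperparameters[[p]])
    }
    hp[[p]] <- hyperparameters[[p]]
  }
  structure(list(name = name, hyperparameters = hp,
                 needs_scaling = name %in% scaling_models(),
                 seed = as.integer(seed)),
            class = "estimator_spec")
}

#' Build an unfitted estimator from a spec
#'
#' @param spec an [estimator_spec()].
#' @return An unfitted `posture_estimator`; `tabnet` (an optional deep
#'   tabular plug-in slot) raises a capability error since no backend is
#'   bundled.
#' @export
build_estimator <- function(spec) {
  stopifnot(inherits(spec, "estimator_spec"))
  if (spec$name == "tabnet") {
    stop("capability error: the tabnet slot has no bundled implementation; ",
         "register an external backend to use it", call. = FALSE)
  }
  structure(list(spec = spec, fitted = NULL, scaler = NULL),
            class = c(paste0(spec$name, "_estimator"), "posture_estimator"))
}

#' Hyperparameters of a spec or estimator
#' @param x an `estimator_spec` or `posture_estimator`.
#' @return Named list of hyperparameter values, unchanged from the spec.
#' @export
hyperparameters <- function(x) {
  if (inherits(x, "posture_estimator")) x$spec$hyperparameters
  else x$hyperparameters
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, x) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Fit an estimator
#'
#' Common fitting entry point for every candidate. `x` is a feature matrix
#' (or a dataset, in which case the 8 canonical features are extracted) and
#' `y` the label factor. Training is deterministic given the spec seed.
#'
#' @param estimator an unfitted estimator from [build_estimator()], or an
#'   [estimator_spec()] (built on the fly).
#' @param x features; matrix, feature table, or posture dataset.
#' @param y labels (factor or character).
#' @return The fitted estimator.
#' @export
fit_estimator <- function(estimator, x, y) {
  if (inherits(estimator, "estimator_spec")) {
    estimator <- build_estimator(estimator)
  }
  stopifnot(inherits(estimator, "posture_estimator"))
  x <- if (is.matrix(x)) x else feature_matrix(x)
  storage.mode(x) <- "double"
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) {
    stop("degenerate target: training data contain a single class",
         call. = FALSE)
  }
  if (estimator$spec$needs_scaling) {
    estimator$scaler <- fit_scaler(x)
    x <- apply_scaler(estimator$scaler, x)
  }
  estimator$levels <- levels(y)
  estimator$fitted <- fit_backend(estimator$spec, x, y)
  estimator
}

fit_backend <- function(spec, x, y) {
  hp <- spec$hyperparameters
  seed <- spec$seed
  nlev <- nlevels(y)
  switch(spec$name,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      params <- list(objective = "multi:softprob", num_class = nlev,
                     eta = hp$learning_rate, max_depth = hp$max_depth,
                     nthread = 1, seed = seed)
      xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                         verbose = 0)
    },
    rf = {
      ranger::ranger(x = x, y = y, num.trees = hp$n_estimators,
                     max.depth = hp$max_depth,
                     min.node.size = hp$min_samples_split,
                     min.bucket = hp$min_samples_leaf,
                     probability = TRUE, seed = seed, num.threads = 1)
    },
    svm = {
      kern <- switch(hp$kernel,
                     rbf = "rbfdot", poly = "polydot", linear = "vanilladot")
      kpar <- switch(hp$kernel,
                     rbf = list(sigma = hp$Gamma),
                     poly = list(degree = 3, scale = 1, offset = 1),
                     linear = list())
      with_seed(seed, kernlab::ksvm(x, y, type = "C-svc", kernel = kern,
                                    kpar = kpar, C = hp$C,
                                    prob.model = TRUE, scaled = FALSE))
    },
    elm = {
      fit_elm(x, y, n_neurons = hp$n_neurons,
              activation = hp$activation_func,
              ridge = hp$ridge %||% 1e-6, seed = seed)
    },
    mlp = {
      with_seed(seed, nnet::nnet(x, nnet::class.ind(y),
                                 size = hp$hidden_units %||% 100L,
                                 decay = hp$alpha, softmax = TRUE,
                                 maxit = hp$maxit %||% 300L,
                                 MaxNWts = 100000, trace = FALSE))
    },
    dndt = {
      cfg <- dndt_config(num_trees = hp$num_trees, tree_depth = hp$tree_depth,
                         learning_rate = hp$learning_rate,
                         batch_size = hp$batch_size,
                         max_features_per_tree = hp$max_features_per_tree %||% 4L,
                         epochs = hp$epochs %||% 200L,
                         tau = hp$tau %||% 0.1,
                         tau_end = hp$tau_end, seed = seed)
      fit_dndt(x, y, cfg)
    },
    stop("no backend for model ", spec$name, call. = FALSE)
  )
}

#' Predict with a fitted estimator
#'
#' @param object fitted `posture_estimator`.
#' @param newdata features (matrix, feature table or posture dataset).
#' @param type `"class"` for hard labels, `"prob"` for the class-probability
#'   matrix (columns in label-code order, rows summing to 1).
#' @param ... unused.
#' @export
predict.posture_estimator <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$fitted)) {
    stop("state error: estimator is not fitted", call. = FALSE)
  }
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  storage.mode(x) <- "double"
  x <- apply_scaler(object$scaler, x)
  p <- predict_backend(object, x)
  colnames(p) <- object$levels
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

predict_backend <- function(object, x) {
  fit <- object$fitted
  nlev <- length(object$levels)
  switch(object$spec$name,
    xgboost = {
      raw <- predict(fit, xgboost::xgb.DMatrix(x))
      if (is.matrix(raw)) raw else matrix(raw, ncol = nlev, byrow = TRUE)
    },
    rf = {
      p <- predict(fit, data = x, num.threads = 1)$predictions
      p[, object$levels, drop = FALSE]
    },
    svm = {
      p <- kernlab::predict(fit, x, type = "probabilities")
      p[, object$levels, drop = FALSE]
    },
    elm = predict_elm(fit, x),
    mlp = {
      p <- predict(fit, x, type = "raw")
      p[, object$levels, drop = FALSE]
    },
    dndt = predict(fit, x, type = "prob")[, object$levels, drop = FALSE]
  )
}

#' Fit every candidate on one split and score on the test part
#'
#' Each spec is fitted on the identical training rows and scored with the
#' five metrics on the identical test rows. A model that fails to fit is
#' recorded with its error message and the remaining models proceed.
#'
#' @param specs list of [estimator_spec()]s (named or not; names default to
#'   the model names).
#' @param train,test labeled posture datasets or feature tables.
#' @param average metric averaging mode, see [score_confusion()].
#' @return List with `metrics` (data frame, one row per fitted model),
#'   `predictions` (named list of label factors), `probabilities` (named
#'   list of matrices), `errors` (named character of failures).
#' @export
fit_predict_all <- function(specs, train, test, average = "macro") {
  stopifnot(length(specs) > 0)
  nm <- names(specs) %||% vapply(specs, function(s) s$name, "")
  if (is.null(names(specs))) names(specs) <- nm
  xtr <- feature_matrix(train)
  xte <- feature_matrix(test)
  ytr <- train$label
  yte <- test$label
  metrics <- list()
  preds <- list()
  probs <- list()
  errors <- character(0)
  for (nm_i in names(specs)) {
    res <- tryCatch({
      est <- fit_estimator(specs[[nm_i]], xtr, ytr)
      pr <- predict(est, xte, type = "prob")
      cl <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                   levels = levels(yte))
      list(metrics = score_predictions(yte, cl, average = average),
           class = cl, prob = pr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm_i]] <- conditionMessage(res)
    } else {
      metrics[[nm_i]] <- res$metrics
      preds[[nm_i]] <- res$class
      probs[[nm_i]] <- res$prob
    }
  }
  mt <- if (length(metrics) > 0) {
    cbind(data.frame(model = names(metrics)),
          as.data.frame(do.call(rbind, metrics)))
  } else {
    data.frame(model = character(0))
  }
  rownames(mt) <- NULL
  list(metrics = mt, predictions = preds, probabilities = probs,
       errors = errors)
}
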