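# Sequential model-based (Bayesian) hyperparameter optimization over mixed
# continuous / integer / categorical spaces. The surrogate is a Gaussian
# process (kernlab::gausspr) on the unit-cube encoding of the space, seeded
# with a maximin Latin hypercube design; proposals maximize expected
# improvement over random candidate draws.

#' Search-space dimensions
#'
#' Constructors for the three dimension kinds of a hyperparameter search
#' space: a continuous interval, an integer range, and a categorical set.
#'
#' @param name hyperparameter name.
#' @param lower,upper finite bounds (inclusive).
#' @param values vector of admissible categorical values.
#' @return An `hpo_dim` descriptor.
#' @export
dim_real <- function(name, lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  structure(list(name = name, type = "real", lower = lower, upper = upper),
            class = "hpo_dim")
}

#' @rdname dim_real
#' @export
dim_int <- function(name, lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  structure(list(name = name, type = "int", lower = as.integer(lower),
                 upper = as.integer(upper)), class = "hpo_dim")
}

#' @rdname dim_real
#' @export
dim_cat <- function(name, values) {
  stopifnot(length(values) >= 1)
  structure(list(name = name, type = "cat", values = values),
            class = "hpo_dim")
}

validate_space <- function(space) {
  stopifnot(length(space) >= 1)
  for (d in space) {
    if (!inherits(d, "hpo_dim")) stop("search space entries must be hpo_dim",
                                      call. = FALSE)
  }
  stats::setNames(space, vapply(space, function(d) d$name, ""))
}

# unit-cube [0,1] value -> native value of one dimension
decode_dim <- function(dm, u) {
  u <- min(max(u, 0), 1)
  switch(dm$type,
    real = dm$lower + u * (dm$upper - dm$lower),
    int = as.integer(round(dm$lower + u * (dm$upper - dm$lower))),
    cat = dm$values[[min(length(dm$values), max(1L, ceiling(u * length(dm$values))))]]
  )
}

decode_point <- function(space, u) {
  stats::setNames(lapply(seq_along(space), function(j) decode_dim(space[[j]], u[j])),
                  names(space))
}

point_in_space <- function(space, params) {
  all(vapply(names(space), function(nm) {
    dm <- space[[nm]]
    v <- params[[nm]]
    switch(dm$type,
      real = v >= dm$lower && v <= dm$upper,
      int = v >= dm$lower && v <= dm$upper && v == round(v),
      cat = v %in% dm$values
    )
  }, logical(1)))
}

expected_improvement <- function(mu, sdv, best) {
  sdv <- pmax(sdv, 1e-12)
  imp <- best - mu
  z <- imp / sdv
  imp * stats::pnorm(z) + sdv * stats::dnorm(z)
}

#' Minimize a black-box objective by Bayesian optimization
#'
#' Runs `n_iterations` sequential evaluations of `objective` over `space`:
#' an initial maximin Latin-hypercube design (which stratifies every
#' dimension, so small categorical sets are covered), then Gaussian-process
#' surrogate fits with expected-improvement proposals. Every evaluated point
#' lies inside the space; the run is reproducible given `seed`.
#'
#' @param objective function taking a named list of hyperparameter values
#'   and returning a finite scalar to minimize.
#' @param space named list of [dim_real()]/[dim_int()]/[dim_cat()] entries.
#' @param n_iterations total evaluation budget (at least 10; the surrogate
#'   needs seeding points).
#' @param seed integer seed.
#' @param n_init size of the initial design (default `min(10, budget/2)`).
#' @param n_candidates random candidates scored per proposal step.
#' @return An `hpo_result`: `best_params`, `best_objective`, `history`
#'   (data frame of evaluated params and objectives), `n_iterations`,
#'   `seed`.
#' @export
bayes_optimize <- function(objective, space, n_iterations = 200, seed = 0L,
                           n_init = NULL, n_candidates = 256) {
  space <- validate_space(space)
  if (n_iterations < 10) {
    stop("config error: n_iterations must be at least 10", call. = FALSE)
  }
  d <- length(space)
  n_init <- n_init %||% max(4L, min(10L, floor(n_iterations / 2)))
  with_seed(seed, {
    u_mat <- matrix(NA_real_, n_iterations, d)
    u_mat[seq_len(n_init), ] <- lhs::maximinLHS(n_init, d)
    objs <- rep(NA_real_, n_iterations)
    params_list <- vector("list", n_iterations)
    for (i in seq_len(n_init)) {
      params_list[[i]] <- decode_point(space, u_mat[i, ])
      objs[i] <- objective(params_list[[i]])
    }
    for (i in (n_init + 1):n_iterations) {
      seen_u <- u_mat[seq_len(i - 1), , drop = FALSE]
      seen_y <- objs[seq_len(i - 1)]
      cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      u_next <- propose_ei(seen_u, seen_y, cand)
      u_mat[i, ] <- u_next
      params_list[[i]] <- decode_point(space, u_next)
      objs[i] <- objective(params_list[[i]])
    }
    history <- cbind(
      do.call(rbind, lapply(params_list, function(p) {
        as.data.frame(lapply(p, function(v) if (is.numeric(v)) v else as.character(v)))
      })),
      objective = objs
    )
    best_i <- which.min(objs)
    structure(list(best_params = params_list[[best_i]],
                   best_objective = objs[best_i],
                   history = history,
                   n_iterations = n_iterations,
                   seed = as.integer(seed)),
              class = "hpo_result")
  })
}

# GP surrogate + expected improvement; random proposal if the surrogate
# cannot be fit (e.g. a constant objective so far).
propose_ei <- function(seen_u, seen_y, cand) {
  if (stats::sd(seen_y) < 1e-12) return(cand[1, ])
  y_s <- (seen_y - mean(seen_y)) / stats::sd(seen_y)
  gp <- tryCatch(
    suppressWarnings(suppressMessages(
      kernlab::gausspr(x = seen_u, y = y_s, variance.model = TRUE,
                       var = 1e-4, tol = 1e-6)
    )),
    error = function(e) NULL
  )
  if (is.null(gp)) return(cand[1, ])
  mu <- tryCatch(as.numeric(kernlab::predict(gp, cand)),
                 error = function(e) NULL)
  sdv <- tryCatch(as.numeric(kernlab::predict(gp, cand, type = "sdeviation")),
                  error = function(e) NULL)
  if (is.null(mu) || is.null(sdv)) return(cand[1, ])
  ei <- expected_improvement(mu, sdv, best = min(y_s))
  cand[which.max(ei), ]
}

#' Cross-validated accuracy of a candidate configuration
#'
#' Mean accuracy over stratified K folds of the training data; the tuning
#' objective is its negative, so tuning never touches a held-out test set.
#'
#' @param name model name.
#' @param params named list of hyperparameter values.
#' @param features feature table (with `label`) or posture dataset.
#' @param n_folds number of folds.
#' @param seed integer seed (folds and model randomness).
#' @return Mean fold accuracy.
#' @export
cv_accuracy <- function(name, params, features, n_folds = 5, seed = 0L) {
  x <- feature_matrix(features)
  y <- features$label
  folds <- make_stratified_folds(y, n_folds, seed)
  accs <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    spec <- estimator_spec(name, hyperparameters = params, seed = seed)
    est <- fit_estimator(spec, x[tr, , drop = FALSE], y[tr])
    pred <- predict(est, x[!tr, , drop = FALSE], type = "class")
    mean(as.character(pred) == as.character(y[!tr]))
  }, numeric(1))
  mean(accs)
}

#' Tune a candidate model by Bayesian optimization
#'
#' Minimizes the negative mean 5-fold cross-validated accuracy of the named
#' model over its documented search space (or a caller-supplied one).
#'
#' @param name model name.
#' @param data labeled posture dataset or feature table.
#' @param space search space; defaults to [hyperparameter_scopes()] for the
#'   model.
#' @param n_iterations evaluation budget (default 200).
#' @param n_folds folds of the tuning objective.
#' @param seed integer seed.
#' @return An `hpo_result` (see [bayes_optimize()]); `best_params` plug
#'   directly into [estimator_spec()].
#' @export
optimize_hyperparams <- function(name, data, space = NULL,
                                 n_iterations = 200, n_folds = 5, seed = 0L) {
  name <- match.arg(name, model_names())
  space <- space %||% hyperparameter_scopes(name)
  features <- if (all(feature_cols() %in% names(data))) data else extract_features(data)
  objective <- function(params) {
    -cv_accuracy(name, params, features, n_folds = n_folds, seed = seed)
  }
  bayes_optimize(objective, space, n_iterations = n_iterations, seed = seed)
}
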