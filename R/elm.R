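# Extreme learning machine: a single random hidden layer whose input
# weights are frozen at initialization; only the output weights are
# estimated, by ridge-regularized least squares against one-hot targets.

elm_activation <- function(name) {
  switch(name,
    tanh = tanh,
    sigm = function(z) 1 / (1 + exp(-z)),
    stop("unknown ELM activation: ", name, call. = FALSE)
  )
}

#' Fit an extreme learning machine classifier
#'
#' Input weights and biases are drawn uniform(-1, 1) from the seed and never
#' trained; output weights solve `(H'H + ridge I) B = H'Y` with `H` the
#' hidden activations and `Y` one-hot labels. Inputs are expected to be
#' standardized by the caller (the estimator wrapper does this).
#'
#' @param x numeric feature matrix.
#' @param y label factor.
#' @param n_neurons hidden-layer width.
#' @param activation `"tanh"` or `"sigm"`.
#' @param ridge ridge regularization of the least-squares solve.
#' @param seed integer seed for the random projection.
#' @return An `elm_fit` object.
#' @export
fit_elm <- function(x, y, n_neurons = 215L, activation = "tanh",
                    ridge = 1e-6, seed = 0L) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  d <- ncol(x)
  act <- elm_activation(activation)
  w <- with_seed(seed, {
    list(W = matrix(stats::runif(d * n_neurons, -1, 1), d, n_neurons),
         b = stats::runif(n_neurons, -1, 1))
  })
  h <- act(sweep(x %*% w$W, 2, w$b, "+"))
  yh <- nnet::class.ind(y)
  gram <- crossprod(h) + diag(ridge, n_neurons)
  beta <- solve(gram, crossprod(h, yh))
  structure(list(W = w$W, b = w$b, beta = beta, activation = activation,
                 levels = levels(y)),
            class = "elm_fit")
}

# Scores softmaxed into probabilities: monotone in the ELM output scores,
# which is all the downstream stacking and argmax need.
predict_elm <- function(fit, x) {
  act <- elm_activation(fit$activation)
  h <- act(sweep(as.matrix(x) %*% fit$W, 2, fit$b, "+"))
  scores <- h %*% fit$beta
  e <- exp(scores - apply(scores, 1, max))
  p <- e / rowSums(e)
  colnames(p) <- fit$levels
  p
}

#' @export
predict.elm_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_elm(object, newdata)
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}
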