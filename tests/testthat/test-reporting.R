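# A feature table where only p3 separates the classes: every other column
# is seeded noise, so any competent model must lean on p3.
single_signal_features <- function(n_per_class = 40, seed = 1) {
  with_seed(seed, {
    n <- n_per_class * 4
    x <- as.data.frame(matrix(runif(n * 8, 1, 2), n, 8))
    names(x) <- feature_cols()
    lab <- rep(posture_levels(), each = n_per_class)
    x$p3 <- rep(c(1, 2, 3, 4), each = n_per_class) + rnorm(n, sd = 0.1)
    x$label <- factor(lab, levels = posture_levels())
    x
  })
}

test_that("permutation importance is zero under the identity permutation", {
  ft <- single_signal_features(10, seed = 2)
  est <- fit_estimator(estimator_spec("elm", seed = 2),
                       as.matrix(ft[feature_cols()]), ft$label)
  one_row <- ft[1, ]
  imp <- permutation_importance(est, one_row, n_permutations = 3, seed = 2)
  expect_equal(unname(imp), rep(0, 8)) # permuting 1 row is the identity
})

test_that("the signal-carrying feature dominates every model row", {
  ft <- single_signal_features(40, seed = 3)
  x <- as.matrix(ft[feature_cols()])
  fits <- list(
    xgboost = fit_estimator(estimator_spec("xgboost", list(n_estimators = 50L),
                                           seed = 3), x, ft$label),
    svm = fit_estimator(estimator_spec("svm", seed = 3), x, ft$label),
    dndt = fit_estimator(fast_dndt_spec(seed = 3, epochs = 40L), x, ft$label)
  )
  imp <- feature_importance(fits, ft, n_permutations = 5, seed = 3)
  expect_equal(unname(rowSums(imp)), rep(1, 4), tolerance = 1e-6)
  for (r in seq_len(nrow(imp))) {
    expect_equal(names(imp)[which.max(imp[r, ])], "p3")
  }
  expect_equal(unname(unlist(imp["average", ])),
               unname(colMeans(as.matrix(imp[1:3, ]))))
})

test_that("a constant predictor is flagged degenerate and made uniform", {
  .S3method("predict", "constant_model",
            function(object, newdata, type = "class", ...) {
              factor(rep("supine", nrow(newdata)), levels = posture_levels())
            })
  ft <- single_signal_features(5, seed = 4)
  est <- structure(list(), class = "constant_model")
  expect_warning(
    imp <- feature_importance(list(flat = est), ft, n_permutations = 2,
                              seed = 4),
    "degenerate"
  )
  expect_equal(unname(unlist(imp["flat", ])), rep(1 / 8, 8))
})

test_that("the bundled importance rows average to the published row", {
  tab <- example_table("importance")
  rows <- as.matrix(tab[feature_cols()])
  rownames(rows) <- tab$model
  avg <- colMeans(rows)
  expect_lt(abs(avg[["p1"]] - 0.2089), 5e-5)
  expect_lt(abs(avg[["p_min"]] - 0.1194), 5e-5)
  expect_equal(max(rows["xgboost", ]), 0.2671)
  expect_equal(max(rows["svm", ]), 0.2463)
  expect_equal(max(rows["dndt", ]), 0.2556)
})

test_that("improvement ranges reproduce the published comparison table", {
  cr <- comparison_report(example_table("ensemble_comparison"))
  expect_equal(cr$ranges$accuracy$min_display, 1.82)
  expect_equal(cr$ranges$accuracy$max_display, 3.99)
  expect_equal(cr$ranges$f1$min_display, 2.2)
  expect_equal(cr$ranges$kappa$max_display, 4.44)
})

test_that("self-comparison yields a (0, 0) range", {
  tab <- data.frame(model = "stacking", accuracy = 0.9, f1 = 0.9, kappa = 0.9)
  cr <- comparison_report(tab)
  expect_equal(cr$ranges$accuracy$min, 0)
  expect_equal(cr$ranges$accuracy$max, 0)
})

test_that("random comparison tables match hand-computed differences", {
  set.seed(5)
  tab <- data.frame(model = c("a", "b", "c", "stacking"),
                    accuracy = runif(4, 0.8, 0.95),
                    f1 = runif(4, 0.8, 0.95),
                    kappa = runif(4, 0.8, 0.95))
  cr <- comparison_report(tab)
  manual <- 100 * (tab$accuracy[4] - tab$accuracy[1:3])
  expect_equal(cr$improvements$accuracy, manual)
  expect_equal(cr$ranges$accuracy$min, min(manual))
  expect_equal(cr$ranges$accuracy$max, max(manual))
})

test_that("schema errors name what is missing", {
  tab <- data.frame(model = c("a", "stacking"), accuracy = c(0.9, 0.95))
  expect_error(comparison_report(tab), "schema error.*f1")
  tab2 <- data.frame(model = "a", accuracy = 0.9, f1 = 0.9, kappa = 0.9)
  expect_error(comparison_report(tab2), "schema error.*stacking")
})
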