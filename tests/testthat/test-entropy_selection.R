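test_that("extreme dispersion concentrates all weight on one metric", {
  sm <- composite_scores(matrix(c(1, 0), ncol = 1,
                                dimnames = list(c("a", "b"), "m")))
  expect_equal(unname(sm$Z[, 1]), c(1, 0))
  expect_equal(unname(sm$entropy), 0)
  expect_equal(unname(sm$weights), 1)
  expect_equal(unname(sm$scores), c(1, 0))
})

test_that("identical rows receive identical scores", {
  x <- matrix(c(0.9, 0.5, 0.9, 0.5, 0.7, 0.9), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  sm <- composite_scores(x)
  expect_equal(sm$scores[["a"]], sm$scores[["b"]])
})

test_that("random matrices match the literal step-by-step oracle to 12 decimals", {
  set.seed(12)
  for (r in 1:10) {
    x <- matrix(runif(15), 5, 3,
                dimnames = list(paste0("m", 1:5), paste0("c", 1:3)))
    sm <- composite_scores(x)
    oracle <- entropy_weight_oracle(x)
    expect_equal(unname(sm$scores), oracle$S, tolerance = 1e-12)
    expect_equal(unname(sm$weights), oracle$w, tolerance = 1e-12)
    expect_equal(unname(sm$entropy), oracle$E, tolerance = 1e-12)
  }
})

test_that("weights form a simplex and entropies and scores stay in range", {
  set.seed(13)
  for (r in 1:20) {
    m <- sample(3:6, 1)
    n <- sample(2:5, 1)
    x <- matrix(runif(m * n), m, n)
    sm <- composite_scores(x)
    expect_equal(sum(sm$weights), 1, tolerance = 1e-12)
    expect_true(all(sm$entropy >= 0 & sm$entropy <= 1 + 1e-12))
    expect_true(all(sm$scores >= 0 & sm$scores <= 1 + 1e-12))
  }
})

test_that("scores are invariant to positive affine rescaling of a column", {
  set.seed(14)
  x <- matrix(runif(20), 5, 4)
  x2 <- x
  x2[, 2] <- 7 * x2[, 2] + 3
  expect_equal(composite_scores(x)$scores, composite_scores(x2)$scores,
               tolerance = 1e-12)
})

test_that("raising one model's metric never lowers its score", {
  set.seed(15)
  for (r in 1:10) {
    x <- matrix(runif(20, 0.2, 0.8), 5, 4)
    j <- sample(4, 1)
    # pick a model strictly inside the column extremes so they are unchanged
    inner <- which(x[, j] > min(x[, j]) & x[, j] < max(x[, j]))
    if (length(inner) == 0) next
    i <- inner[1]
    x2 <- x
    x2[i, j] <- min(max(x[, j]) - 1e-9, x[i, j] + 0.5 * (max(x[, j]) - x[i, j]))
    s1 <- composite_scores(x)$scores[i]
    s2 <- composite_scores(x2)$scores[i]
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("constant columns get zero weight and degenerate input errors", {
  x <- cbind(c(0.5, 0.5, 0.5), c(0.1, 0.5, 0.9))
  sm <- composite_scores(x)
  expect_equal(unname(sm$weights), c(0, 1))
  expect_error(composite_scores(x[1, , drop = FALSE]), "degenerate")
  x_bad <- x
  x_bad[1, 1] <- NA
  expect_error(composite_scores(x_bad), "validation error")
})

test_that("selection orders by score with deterministic tie-breaks", {
  s <- c(a = 0.3, b = 0.9, c = 0.9, d = 0.1)
  expect_equal(select_top_k(s, 2), c("b", "c")) # tie: earlier name wins
  expect_equal(select_top_k(s, 4), c("b", "c", "a", "d"))
  expect_error(select_top_k(s, 5), "selection error")
})

test_that("the bundled candidate table ranks the models as published", {
  sm <- composite_scores(example_table("candidate_metrics"))
  ranked <- names(sort(sm$scores, decreasing = TRUE))
  expect_equal(ranked, c("xgboost", "dndt", "svm", "tabnet", "rf", "elm", "mlp"))
  expect_equal(select_top_k(sm, 3), c("xgboost", "dndt", "svm"))
})

test_that("one repeat of candidate evaluation equals a single fit on that split", {
  ft <- extract_features(easy_data(25, seed = 16))
  specs <- list(elm = estimator_spec("elm", seed = 16),
                dndt = fast_dndt_spec(seed = 16, epochs = 20L))
  ev <- evaluate_candidates(specs, ft, n_repeats = 1, seed_base = 4)
  sp <- split_dataset(ft, test_fraction = 0.2, stratified = TRUE, seed = 5)
  direct <- fit_predict_all(specs, sp$train, sp$test)
  expect_equal(ev$mean_metrics, direct$metrics)
  ev2 <- evaluate_candidates(specs, ft, n_repeats = 1, seed_base = 4)
  expect_identical(ev$mean_metrics, ev2$mean_metrics)
})
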