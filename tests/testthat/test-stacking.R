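test_that("meta-feature blocks have the contracted shape and simplex rows", {
  sp <- easy_split(25, seed = 1)
  specs <- list(elm = estimator_spec("elm", seed = 1),
                svm = estimator_spec("svm", seed = 1),
                dndt = fast_dndt_spec(seed = 1, epochs = 20L))
  cfg <- stacking_config(specs, n_folds = 5, seed = 1)
  mf <- build_meta_features(cfg, sp$train, sp$test)
  expect_equal(ncol(mf$Tr), 12) # 3 models x 4 classes
  expect_equal(ncol(mf$Te), 12)
  expect_true(all(mf$fold_id %in% 1:5))
  for (j in 1:3) {
    block <- (j - 1) * 4 + 1:4
    expect_equal(unname(rowSums(mf$Tr[, block])), rep(1, nrow(mf$Tr)),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(mf$Te[, block])), rep(1, nrow(mf$Te)),
                 tolerance = 1e-9)
  }
})

test_that("every out-of-fold row matches a model retrained without its fold", {
  d <- extract_features(easy_data(5, seed = 2)) # N = 20
  spec <- list(elm = estimator_spec("elm", seed = 2))
  cfg <- stacking_config(spec, n_folds = 5, seed = 2)
  mf <- build_meta_features(cfg, d)
  x <- as.matrix(d[feature_cols()])
  for (i in seq_len(nrow(d))) {
    keep <- mf$fold_id != mf$fold_id[i]
    est <- fit_estimator(spec$elm, x[keep, , drop = FALSE], d$label[keep])
    p <- predict(est, x[i, , drop = FALSE], type = "prob")
    expect_equal(unname(mf$Tr[i, ]), unname(as.numeric(p)), tolerance = 1e-12)
  }
})

test_that("test meta-features come from full-train refits, not fold models", {
  d <- extract_features(easy_data(10, seed = 3))
  sp <- split_dataset(d, seed = 3)
  spec <- list(elm = estimator_spec("elm", seed = 3))
  cfg <- stacking_config(spec, seed = 3)
  # duplicate a training sample into the test set: its Te row (full-train
  # model) differs from its Tr row (out-of-fold model)
  test_dup <- rbind(sp$test, sp$train[1, ])
  mf <- build_meta_features(cfg, sp$train, test_dup)
  expect_false(identical(unname(mf$Te[nrow(test_dup), ]), unname(mf$Tr[1, ])))
})

test_that("corrupting test labels changes no training artifact, bit for bit", {
  sp <- easy_split(20, seed = 4)
  specs <- list(elm = estimator_spec("elm", seed = 4),
                svm = estimator_spec("svm", seed = 4))
  cfg <- stacking_config(specs, seed = 4)
  test_bad <- sp$test
  test_bad$label <- sample(test_bad$label)
  mf1 <- build_meta_features(cfg, sp$train, sp$test)
  mf2 <- build_meta_features(cfg, sp$train, test_bad)
  expect_identical(serialize(mf1$Tr, NULL), serialize(mf2$Tr, NULL))
  st1 <- fit_stack(cfg, sp$train)
  st2 <- fit_stack(cfg, sp$train)
  expect_identical(serialize(st1$meta$fit$beta, NULL),
                   serialize(st2$meta$fit$beta, NULL))
})

test_that("permuting the base-model list permutes blocks and keeps accuracy", {
  sp <- easy_split(25, seed = 5)
  specs <- list(elm = estimator_spec("elm", seed = 5),
                svm = estimator_spec("svm", seed = 5))
  cfg_ab <- stacking_config(specs, seed = 5)
  cfg_ba <- stacking_config(specs[c(2, 1)], seed = 5)
  mf_ab <- build_meta_features(cfg_ab, sp$train, sp$test)
  mf_ba <- build_meta_features(cfg_ba, sp$train, sp$test)
  expect_equal(mf_ab$Tr[, 1:4], mf_ba$Tr[, 5:8], ignore_attr = TRUE)
  expect_equal(mf_ab$Tr[, 5:8], mf_ba$Tr[, 1:4], ignore_attr = TRUE)
  acc <- function(cfg) {
    st <- fit_stack(cfg, sp$train)
    mean(predict(st, sp$test) == sp$test$label)
  }
  expect_equal(acc(cfg_ab), acc(cfg_ba))
})

test_that("a single-base stack stays within 2 points of the base model", {
  sp <- easy_split(40, seed = 6)
  spec <- list(svm = estimator_spec("svm", seed = 6))
  st <- fit_stack(stacking_config(spec, seed = 6), sp$train)
  stack_acc <- mean(predict(st, sp$test) == sp$test$label)
  est <- fit_estimator(spec$svm, sp$train, sp$train$label)
  base_acc <- mean(predict(est, sp$test) == sp$test$label)
  expect_gte(stack_acc, base_acc - 0.02)
})

test_that("stack predictions are deterministic, simplex, and in-vocabulary", {
  sp <- easy_split(25, seed = 7)
  specs <- list(elm = estimator_spec("elm", seed = 7),
                dndt = fast_dndt_spec(seed = 7, epochs = 20L))
  cfg <- stacking_config(specs, seed = 7)
  st1 <- fit_stack(cfg, sp$train)
  st2 <- fit_stack(cfg, sp$train)
  expect_identical(predict(st1, sp$test, type = "prob"),
                   predict(st2, sp$test, type = "prob"))
  p <- predict(st1, sp$test, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  one <- predict(st1, sp$test[1, ], type = "class")
  expect_true(as.character(one) %in% posture_levels())
})

test_that("hard-label meta-features are one-hot and still learnable", {
  sp <- easy_split(25, seed = 8)
  specs <- list(elm = estimator_spec("elm", seed = 8))
  cfg <- stacking_config(specs, meta_features = "labels", seed = 8)
  mf <- build_meta_features(cfg, sp$train, sp$test)
  expect_true(all(mf$Tr %in% c(0, 1)))
  expect_equal(unname(rowSums(mf$Tr)), rep(1, nrow(mf$Tr)))
  st <- fit_stack(cfg, sp$train)
  expect_gte(mean(predict(st, sp$test) == sp$test$label), 0.9)
})

test_that("folding errors name the class missing from a training fold", {
  # a class with a single member cannot appear in every training fold
  y <- factor(c("supine", "supine", "side", "side", "fetus", "fetus", "prone"),
              levels = posture_levels())
  expect_error(make_stratified_folds(y, 2, seed = 1),
               "folding error.*prone")
  # two members per class spread over 2 folds is fine
  y2 <- factor(rep(posture_levels(), each = 2), levels = posture_levels())
  folds <- make_stratified_folds(y2, 2, seed = 1)
  expect_true(all(folds %in% 1:2))
})
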