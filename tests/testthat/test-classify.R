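separable_features <- function(n_per = 8, gap = 6, seed = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 4), n_per, 4),
             matrix(rnorm(n_per * 4, mean = gap), n_per, 4))
  list(x = x, y = rep(c("Normal", "SED"), each = n_per))
}

test_that("linearly separable classes are classified perfectly under LOOCV", {
  d <- separable_features()
  for (kind in c("svm", "knn", "random_forest", "mlp")) {
    rep <- run_classification(d$x, d$y, swp_classifier_spec(kind))
    expect_equal(rep$accuracy, 1)
  }
})

test_that("KNN clamps k to the training size with a warning and breaks ties", {
  tr <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), 4, 2, byrow = TRUE)
  expect_warning(
    p <- swpkit:::knn_predict(tr, c("Normal", "Normal", "SED", "SED"),
                              matrix(c(0.5, 0.5), 1, 2), k = 5),
    class = "swp_warning")
  expect_equal(unname(p), "Normal")   # 2-2 tie broken by the nearest point
})

test_that("classification runs are reproducible under a fixed seed", {
  d <- separable_features(gap = 1.5)
  r1 <- run_classification(d$x, d$y, swp_classifier_spec("random_forest"),
                           seed = 5)
  r2 <- run_classification(d$x, d$y, swp_classifier_spec("random_forest"),
                           seed = 5)
  expect_identical(attr(r1, "predictions"), attr(r2, "predictions"))
  r3 <- run_classification(d$x, d$y, swp_classifier_spec("mlp"), seed = 5)
  r4 <- run_classification(d$x, d$y, swp_classifier_spec("mlp"), seed = 5)
  expect_identical(attr(r3, "predictions"), attr(r4, "predictions"))
})

test_that("augmented samples train but are never tested under LOOCV", {
  d <- separable_features(n_per = 5)
  aug_x <- matrix(rnorm(40, mean = 3), 10, 4)
  aug_y <- rep(c("Normal", "SED"), each = 5)
  rep <- run_classification(d$x, d$y, swp_classifier_spec("knn"),
                            swp_split_protocol("loocv"),
                            augmented_x = aug_x, augmented_y = aug_y)
  preds <- attr(rep, "predictions")
  expect_equal(rep$n, nrow(d$x))             # originals only in test sets
  expect_setequal(preds$index, seq_len(nrow(d$x)))

  # pooling augmented samples into the CV enlarges the evaluated set
  pooled <- run_classification(d$x, d$y, swp_classifier_spec("knn"),
                               swp_split_protocol("loocv",
                                                  augment_training_only = FALSE),
                               augmented_x = aug_x, augmented_y = aug_y)
  expect_equal(pooled$n, nrow(d$x) + nrow(aug_x))
})

test_that("k-fold protocol evaluates every sample exactly once", {
  d <- separable_features(n_per = 10)
  rep <- run_classification(d$x, d$y, swp_classifier_spec("svm"),
                            swp_split_protocol("kfold", folds = 5), seed = 3)
  preds <- attr(rep, "predictions")
  expect_setequal(preds$index, seq_len(nrow(d$x)))
  expect_equal(rep$n, nrow(d$x))
})

test_that("shape and config errors are raised before fitting", {
  d <- separable_features(n_per = 4)
  expect_error(run_classification(d$x, d$y[-1]), class = "swp_shape_error")
  expect_error(run_classification(d$x, d$y,
                                  augmented_x = matrix(0, 2, 3),
                                  augmented_y = c("Normal", "SED")),
               class = "swp_shape_error")
  expect_error(swp_classifier_spec("svm", bogus = 1),
               class = "swp_config_error")
  expect_error(swp_split_protocol("kfold", folds = 1),
               class = "swp_config_error")
})

test_that("the evaluation grid covers every feature-classifier cell", {
  traces <- tiny_traces(8)
  grid <- run_grid(traces,
                   feature_kinds = c("time_domain", "deriv_1st", "integral"),
                   classifier_kinds = c("svm", "knn", "random_forest",
                                        "mlp"),
                   methods = "none")
  expect_equal(nrow(grid), 12)
  expect_true(all(!is.na(grid$accuracy)))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))

  withaug <- run_grid(traces, feature_kinds = "deriv_1st",
                      classifier_kinds = "random_forest",
                      methods = c("none", "aae"),
                      n_per_group = 3, cfg = fast_aae_cfg(epochs = 6))
  expect_equal(nrow(withaug), 2)
  expect_setequal(withaug$method, c("none", "aae"))

  expect_error(run_grid(traces, feature_kinds = character()),
               class = "swp_config_error")
})
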