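# Small, fully separable synthetic feature sets for exercising the fold
# protocol without the cost of the cohort simulator.
toy_training_data <- function(n_samples = 10, per_sample = 30,
                              somatic_frac = 0.3, seed = 99,
                              separable = TRUE) {
  set.seed(seed)
  n <- n_samples * per_sample
  sample_ids <- rep(sprintf("T%02d", seq_len(n_samples)), each = per_sample)
  labels <- ifelse(runif(n) < somatic_frac, "somatic", "germline")
  base <- as.data.frame(matrix(rnorm(n * 31), n, 31))
  names(base) <- feature_names()
  if (separable) {
    base$gnomad_present <- as.integer(labels == "germline")
  }
  list(features = base, labels = labels, sample_ids = sample_ids)
}

test_that("the cohort split is seeded, disjoint and exhaustive", {
  ids <- sprintf("S%03d", 1:462)
  s1 <- split_cohort(ids, n_train = 100, seed = 5)
  s2 <- split_cohort(ids, n_train = 100, seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(s1$train_ids), 100)
  expect_equal(length(s1$test_ids), 362)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), ids)
  expect_error(split_cohort(ids[1:50], n_train = 100), "fewer")
  s0 <- split_cohort(ids, n_train = 0, seed = 1)
  expect_length(s0$train_ids, 0)
  expect_setequal(s0$test_ids, ids)
})

test_that("folds partition the training samples into equal validation blocks", {
  ids <- sprintf("S%03d", 1:100)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_length(folds, 5)
  val_all <- unlist(lapply(folds, `[[`, "validation_sample_ids"))
  expect_setequal(val_all, ids)
  expect_equal(length(val_all), 100)       # disjoint blocks
  for (f in folds) {
    expect_length(f$validation_sample_ids, 20)
    expect_length(f$train_sample_ids, 80)
    expect_length(intersect(f$train_sample_ids, f$validation_sample_ids), 0)
  }
  expect_identical(make_folds(ids, 5, seed = 3), folds)
  expect_error(make_folds(ids[1:99], k = 5), "divide")
})

test_that("a separable cohort trains to perfect fold validation metrics", {
  toy <- toy_training_data()
  folds <- make_folds(unique(toy$sample_ids), k = 5, seed = 1)
  model <- train_ensemble(toy$features, toy$labels, toy$sample_ids, folds,
                          seed = 11)
  expect_s3_class(model, "somatic_ensemble")
  expect_length(model$forests, 5)
  expect_true(all(model$fold_metrics$precision == 1))
  expect_true(all(model$fold_metrics$recall == 1))
  # prediction is deterministic and respects the feature hash
  p1 <- predict_majority(model, toy$features)
  p2 <- predict_majority(model, toy$features)
  expect_identical(p1, p2)
  expect_equal(as.character(p1),
               ifelse(toy$features$gnomad_present == 1, "germline", "somatic"))
  scrambled <- toy$features[, rev(names(toy$features))]
  expect_error(predict_majority(model, scrambled), "feature ordering")
})

test_that("degenerate folds are rejected", {
  toy <- toy_training_data(n_samples = 5, per_sample = 10)
  toy$labels[] <- "germline"
  folds <- make_folds(unique(toy$sample_ids), k = 5, seed = 1)
  expect_error(train_ensemble(toy$features, toy$labels, toy$sample_ids,
                              folds), "one class")
})

test_that("majority vote is defined for every pattern and has no ties", {
  for (mask in 0:31) {
    votes <- as.integer(intToBits(mask))[1:5]
    label <- majority_label(votes)
    expect_true(label %in% c("somatic", "germline"))
    expect_identical(label, if (sum(votes) >= 3) "somatic" else "germline")
  }
})

test_that("feature importance averages to a unit-sum ranking with the planted signal first", {
  toy <- toy_training_data(n_samples = 10, per_sample = 60, seed = 4)
  folds <- make_folds(unique(toy$sample_ids), k = 5, seed = 1)
  model <- train_ensemble(toy$features, toy$labels, toy$sample_ids, folds,
                          seed = 2)
  imp <- feature_importance(model)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$feature[1], "gnomad_present")
})

test_that("performance is insensitive to the tree count in the 30-100 range", {
  toy <- toy_training_data(n_samples = 10, per_sample = 80, seed = 21,
                           separable = FALSE)
  # partially informative signal: overlapping Gaussians
  toy$features$tumor_f <- rnorm(length(toy$labels),
                                ifelse(toy$labels == "somatic", -1, 1), 1.5)
  folds <- make_folds(unique(toy$sample_ids), k = 5, seed = 1)
  m30 <- train_ensemble(toy$features, toy$labels, toy$sample_ids, folds,
                        n_trees = 30, seed = 2)
  m100 <- train_ensemble(toy$features, toy$labels, toy$sample_ids, folds,
                         n_trees = 100, seed = 2)
  d_prec <- abs(median(m30$fold_metrics$precision) -
                  median(m100$fold_metrics$precision))
  d_rec <- abs(median(m30$fold_metrics$recall) -
                 median(m100$fold_metrics$recall))
  expect_lt(d_prec, 0.05)
  expect_lt(d_rec, 0.05)
})

test_that("model archives restore an equivalent ensemble", {
  toy <- toy_training_data(n_samples = 5, per_sample = 20)
  folds <- make_folds(unique(toy$sample_ids), k = 5, seed = 1)
  model <- train_ensemble(toy$features, toy$labels, toy$sample_ids, folds,
                          seed = 7)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- load_model(dir)
  expect_equal(back$feature_hash, model$feature_hash)
  expect_identical(predict_majority(back, toy$features),
                   predict_majority(model, toy$features))
})
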