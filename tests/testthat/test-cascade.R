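test_that("preprocessing windows, normalizes and resamples", {
  spec <- preprocess_spec(c(32, 32))
  expect_true(all(preprocess_slice(matrix(-1000, 32, 32), spec) == 0))
  expect_true(all(preprocess_slice(matrix(2000, 32, 32), spec) == 1))
  expect_true(all(preprocess_slice(matrix(5000, 32, 32), spec) == 1)) # clipped
  expect_error(preprocess_slice(matrix(c(NA, 1:15), 4, 4), spec), "non-finite")

  big <- withr::with_seed(3, matrix(runif(64 * 64, -1000, 2000), 64, 64))
  small <- preprocess_slice(big, spec)
  expect_identical(dim(small), c(32L, 32L))
  win <- (pmin(pmax(big, -1000), 2000) + 1000) / 3000
  expect_lt(abs(mean(small) - mean(win)) / mean(win), 0.01)
})

test_that("the weighted score penalizes by class distance", {
  expect_equal(weighted_classification_score(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(weighted_classification_score(rep(1, 4), rep(4, 4)), 0)
  expect_equal(weighted_classification_score(c(1, 2, 3, 4), c(1, 3, 3, 4)),
               1 - 1 / 12)
  # brute force over random label vectors
  withr::with_seed(10, {
    for (rep in 1:5) {
      t <- sample(1:4, 50, TRUE); p <- sample(1:4, 50, TRUE)
      acc <- 0
      for (j in 1:50) acc <- acc + abs(t[j] - p[j])
      expect_equal(weighted_classification_score(t, p), 1 - acc / (50 * 3))
    }
  })
  expect_error(weighted_classification_score(integer(), integer()), "empty")
  expect_error(weighted_classification_score(1:3, 1:4), "equal length")
  expect_error(weighted_classification_score(c(0, 1), c(1, 1)), "1..n_classes")
})

test_that("patient splits are disjoint, exhaustive, and patient-level", {
  ids <- rep(sprintf("P%02d", 1:10), each = 20)
  sp <- patient_split(ids, seed = 4)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), unique(ids))
  expect_length(sp$val, 1L)
  expect_length(sp$test, 2L)  # round(0.15 * 10)
  expect_error(patient_split(c("a", "b")), "at least 3")
})

test_that("a trained cascade has 5 estimators and invokes 2 per slice", {
  model <- mini_model()
  expect_length(model$regressors, 4L)
  td <- tidy(model)
  expect_equal(nrow(td), 5L)
  expect_equal(td$task, c("classification", rep("regression", 4)))
  expect_equal(glance(model)$n_estimators, 5L)

  p <- tiny_pair(seed = 30)
  reset_invocations(model)
  pred <- predict_volume(model, p$pair$sct)
  expect_equal(nrow(pred$records), 6L)
  expect_equal(cascade_invocations(model), 12L)  # 2 per slice
  # pMAE volume mirrors the records slice by slice
  for (i in 1:6) {
    expect_equal(unique(as.vector(pred$pmae[, , i])),
                 pred$records$mae_predicted[i])
  }
  expect_true(all(pred$records$mae_predicted >= 0 &
                    pred$records$mae_predicted <= model$scheme$saturation))
})

test_that("routing follows the classifier argmax and inference is deterministic", {
  model <- mini_model()
  p <- tiny_pair(seed = 31)
  x <- sctqc:::corpus_tensor(
    build_corpus(p$pair, min_body_fraction = 0), model$preprocess)
  probs <- estimator_predict(model$classifier, x)
  expected_cls <- max.col(probs, ties.method = "first")
  rec <- sctqc:::predict_batch(model, x)
  expect_equal(rec$class_predicted, expected_cls)
  # the routed regressor's rescaled output is what predict reports
  for (r in seq_len(nrow(rec))) {
    est <- model$regressors[[rec$class_predicted[r]]]
    raw <- estimator_predict(est, x[r, , , , drop = FALSE])
    val <- est$range[["lo"]] + raw * (est$range[["hi"]] - est$range[["lo"]])
    expect_equal(rec$mae_predicted[r],
                 min(max(val, 0), model$scheme$saturation))
  }
  again <- sctqc:::predict_batch(model, x)
  expect_identical(rec, again)

  one <- predict_slice(model, unclass(p$pair$sct)[, , 3])
  expect_equal(nrow(one), 1L)
})

test_that("regressors see exactly the slices inside their relaxed range", {
  mr <- bin_scheme(c(0, 47, 54, 68, 100))
  # a label of 50 HU falls in ranges 1, 2 and 3 but not 4
  expect_equal(regression_membership(50, mr), c(1L, 2L, 3L))
  corpus <- mini_corpus()
  scheme <- compute_classification_bins(corpus$mae_gt, saturation = 100)
  sat <- as.numeric(saturate_mae(corpus$mae_gt, 100))
  for (k in 1:4) {
    rr <- scheme$regression_ranges[k, ]
    members <- which(sat >= rr$lo & sat <= rr$hi)
    expect_true(all(vapply(sat[members], function(m)
      k %in% regression_membership(m, scheme), TRUE)))
  }
})

test_that("a regressor trained on constant labels predicts that constant", {
  withr::with_seed(60, {
    n <- 30
    x <- array(runif(n * 32 * 32), c(n, 32, 32, 1))
  })
  spec <- backbone_spec("tiny", out_dim = 1)
  cfg <- desk_train_config(max_epochs = 150L, augment_mirror = FALSE,
                           max_translation_px = 0L)
  # constant 30 HU inside a [0, 52] range, scaled to range units
  est <- train_estimator(x, rep(30 / 52, n), "regression", spec, cfg,
                         train_idx = 1:24, val_idx = 25:30, seed = 3)
  pred_hu <- estimator_predict(est, x) * 52
  expect_true(all(abs(pred_hu - 30) < 1))
})

test_that("a class missing from the training split is rejected", {
  corpus <- mini_corpus()
  # force all labels into one class: scheme quartiles from different data
  sch <- suppressWarnings(bin_scheme(c(0, 96, 97, 98, 100)))
  expect_error(train_classifier(corpus, sch, mini_cfg()), "absent")
})

test_that("cascades survive a save/load round trip", {
  model <- mini_model()
  dir <- withr::local_tempdir()
  save_cascade(model, dir)
  files <- list.files(dir)
  expect_true(all(c("scheme.json", "classifier.json",
                    paste0("regressor_", 1:4, ".json"),
                    "preprocess.json", "config.json") %in% files))
  expect_length(grep("^training_log_", files), 5L)

  back <- load_cascade(dir)
  p <- tiny_pair(seed = 33)
  x <- sctqc:::corpus_tensor(build_corpus(p$pair, min_body_fraction = 0),
                             model$preprocess)
  expect_equal(sctqc:::predict_batch(back, x), sctqc:::predict_batch(model, x),
               tolerance = 1e-12)

  file.remove(file.path(dir, "regressor_3.json"))
  expect_error(load_cascade(dir), "regressor_3.json")
})
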