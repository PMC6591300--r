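train_small <- function(n = 30, seed = 5, ...) {
  ds <- small_preprocessed(n_trials_per_class = n)
  list(data = ds, model = suppressWarnings(train_optical(ds, seed = seed, ...)))
}

test_that("the fused predictor separates seeded synthetic data in-sample", {
  fit <- train_small(n = 50)
  pred <- predict_optical(fit$model, fit$data)
  expect_lte(mean(pred != fit$data$labels), 0.05)
  expect_true(all(pred %in% fit$data$labels))
  # repeated prediction is deterministic
  expect_identical(pred, predict_optical(fit$model, fit$data))
  expect_identical(predict_trial(fit$model, fit$data$trials[[1]]),
                   predict_trial(fit$model, fit$data$trials[[1]]))
})

test_that("bivariate features equal the manual composition of the stages", {
  fit <- train_small(n = 15)
  m <- fit$model
  for (i in c(1, 8, 23)) {
    E <- fit$data$trials[[i]]
    f <- extract_bivariate(m, E)
    f_lda_manual <- project_lda(m$lda,
                                csp_features(apply_spatial_filter(m$csp_trial, E)))
    f_lstm_manual <- lstm_feature(m$lstm,
                                  build_sequence_features(E, m$window,
                                                          m$csp_segment))
    expect_equal(unname(f["f_lda"]), f_lda_manual, tolerance = 1e-10)
    expect_equal(unname(f["f_lstm"]), f_lstm_manual, tolerance = 1e-10)
    std <- attr(f, "standardized")
    expect_equal(unname(std),
                 unname((c(f_lda_manual, f_lstm_manual) - m$feature_center) /
                          m$feature_scale),
                 tolerance = 1e-10)
  }
})

test_that("both feature paths order the classes consistently on test data", {
  cfg_tr <- small_config(n_trials_per_class = 50, noise_seed = 31)
  cfg_te <- small_config(n_trials_per_class = 25, noise_seed = 77)
  tr <- suppressWarnings(preprocess(generate_mi_dataset(cfg_tr)))
  te <- suppressWarnings(preprocess(generate_mi_dataset(cfg_te)))
  m <- suppressWarnings(train_optical(tr, seed = 6))
  feats <- t(vapply(te$trials, function(E) extract_bivariate(m, E), numeric(2)))
  pos <- te$labels == m$classes[1]
  # class-1 mean above class-2 mean on both features
  expect_gt(mean(feats[pos, 1]), mean(feats[!pos, 1]))
  expect_gt(mean(feats[pos, 2]), mean(feats[!pos, 2]))
  # consistent per-trial ordering for >= 90% of test trials on each feature
  thr1 <- mean(c(mean(feats[pos, 1]), mean(feats[!pos, 1])))
  thr2 <- mean(c(mean(feats[pos, 2]), mean(feats[!pos, 2])))
  agree1 <- mean((feats[, 1] > thr1) == pos)
  agree2 <- mean((feats[, 2] > thr2) == pos)
  expect_gte(agree1, 0.9)
  expect_gte(agree2, 0.9)
})

test_that("models round-trip through the single-file container bit-identically", {
  fit <- train_small(n = 15)
  path <- withr::local_tempfile(fileext = ".rds")
  write_optical_model(fit$model, path)
  back <- read_optical_model(path)
  p1 <- predict_optical(fit$model, fit$data)
  p2 <- predict_optical(back, fit$data)
  expect_identical(p1, p2)
  f1 <- extract_bivariate(fit$model, fit$data$trials[[3]])
  f2 <- extract_bivariate(back, fit$data$trials[[3]])
  expect_identical(f1, f2)
})

test_that("without optimization the LSTM uses the default rates", {
  fit <- train_small(n = 15)
  expect_equal(fit$model$lstm_config$learn_rate, 1e-2)
  expect_equal(fit$model$lstm_config$l2, 1e-4)
  expect_null(fit$model$hyper)
})

test_that("training is a pure function of the training split", {
  ds <- small_preprocessed(n_trials_per_class = 20)
  split <- rep(c(TRUE, FALSE), length.out = length(ds))
  train_a <- subset_trials(ds, split)
  m1 <- suppressWarnings(train_optical(train_a, seed = 4))
  # perturb the held-out trials: the model must not change
  ds2 <- ds
  for (i in which(!split)) ds2$trials[[i]] <- ds2$trials[[i]] * 5 + 1
  train_b <- subset_trials(ds2, split)
  m2 <- suppressWarnings(train_optical(train_b, seed = 4))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("ablation modes fit and predict with their single features", {
  ds <- small_preprocessed(n_trials_per_class = 25)
  m_lda <- suppressWarnings(train_optical(ds, mode = "csp_lda", seed = 7))
  expect_null(m_lda$lstm)
  expect_lte(mean(predict_optical(m_lda, ds) != ds$labels), 0.05)
  m_lstm <- suppressWarnings(train_optical(ds, mode = "lstm_only", seed = 7))
  expect_lte(mean(predict_optical(m_lstm, ds) != ds$labels), 0.10)
})

test_that("Bayesian-optimized training respects the box and stores the trace", {
  ds <- small_preprocessed(n_trials_per_class = 12)
  m <- suppressWarnings(train_optical(
    ds, optimize = TRUE, box = hyper_box(budget = 5, seed = 2),
    inner_folds = 3, hyper_objective = "lstm",
    lstm = lstm_config(max_epochs = 20), seed = 8
  ))
  expect_s3_class(m$hyper$trace, "tbl_df")
  expect_equal(nrow(m$hyper$trace), 5L)
  expect_equal(m$lstm_config$learn_rate, m$hyper$best_learn_rate)
  expect_true(m$hyper$best_learn_rate >= 1e-4 && m$hyper$best_learn_rate <= 1e-1)
  expect_true(m$hyper$best_l2 >= 1e-5 && m$hyper$best_l2 <= 1e-3)
})

test_that("stage failures name the failing stage", {
  ds <- small_preprocessed(n_trials_per_class = 5)
  ds$labels <- rep("left", length(ds))
  expect_error(suppressWarnings(train_optical(ds, seed = 1)), "2 classes")
})
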