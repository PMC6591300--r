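#' Train the OPTICAL predictor
#'
#' Fits the full fusion predictor on a preprocessed two-class training set:
#' (1) a whole-trial CSP bank whose log-variance features are reduced to one
#' scalar by Fisher LDA; (2) a second CSP bank learned from the pooled
#' sliding-window segments of the training trials, whose per-window features
#' form the sequence input of a regression LSTM; (3) the two scalars,
#' z-scored with training statistics, feed an RBF-kernel SVM.
#'
#' @param train an [epoched_dataset()] with exactly two classes,
#'   already preprocessed (CAR + band-pass).
#' @param m_pairs CSP filter pairs (default 3, i.e. six filters per bank).
#' @param window optional [window_params()]; defaults to
#'   [default_window_params()] of the trial length.
#' @param lstm an [lstm_config()]; its `learn_rate`/`l2` are overridden when
#'   `optimize = TRUE`.
#' @param optimize run Bayesian optimization of the LSTM learn rate and L2
#'   penalty (inner cross-validation on the training set). With
#'   `optimize = FALSE` the defaults `learn_rate = 1e-2`, `l2 = 1e-4` are
#'   used (the un-optimized OPTICAL* variant).
#' @param box a [hyper_box()] searched when `optimize = TRUE`.
#' @param inner_folds folds of the inner CV scoring each hyper-parameter
#'   candidate (default 10).
#' @param hyper_objective `"optical"` scores candidates by the deployed
#'   fused predictor's inner-CV misclassification; `"lstm"` scores the
#'   cheaper LSTM-feature-only classifier.
#' @param mode which features the SVM consumes: `"fused"` (default) uses
#'   both, `"csp_lda"` only the LDA scalar, `"lstm_only"` only the LSTM
#'   scalar.
#' @param seed seed controlling LSTM initialization and inner-CV folds.
#' @return A `trained_optical_model`.
#' @export
train_optical <- function(train, m_pairs = 3, window = NULL,
                          lstm = lstm_config(), optimize = FALSE,
                          box = hyper_box(), inner_folds = 10,
                          hyper_objective = c("optical", "lstm"),
                          mode = c("fused", "csp_lda", "lstm_only"),
                          seed = 1) {
  stopifnot(inherits(train, "epoched_dataset"))
  mode <- match.arg(mode)
  hyper_objective <- match.arg(hyper_objective)
  classes <- unique(train$labels)
  if (length(classes) != 2L) stop("training set must have exactly 2 classes")
  S <- ncol(train$trials[[1L]])
  if (is.null(window)) window <- default_window_params(S)
  hyper <- NULL
  if (optimize) {
    hyper <- bayes_optimize(
      make_hyper_objective(train, m_pairs, window, lstm, classes,
                           inner_folds, hyper_objective, mode, seed),
      box
    )
    lstm$learn_rate <- hyper$best_learn_rate
    lstm$l2 <- hyper$best_l2
  }
  lstm$init_seed <- as.integer(seed)
  model <- fit_optical_stages(train, m_pairs, window, lstm, classes, mode)
  model$hyper <- hyper
  model
}

# One full fit of all stages with fixed hyper-parameters.
fit_optical_stages <- function(train, m_pairs, window, lstm_cfg, classes,
                               mode) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("OPTICAL training failed in stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  csp_trial <- stage("csp_trial", learn_csp(train, m_pairs, classes))
  feats <- stage("csp_features", csp_feature_matrix(csp_trial, train))
  lda <- stage("lda", fit_lda(feats, train$labels, classes))
  f_lda <- project_lda(lda, feats)

  segs <- stage("segmentation", pool_segments(train, window))
  csp_segment <- stage("csp_segment", learn_csp(segs, m_pairs, classes))
  sequences <- lapply(train$trials, build_sequence_features,
                      p = window, bank = csp_segment)
  lstm_cfg$input_dim <- 2L * csp_segment$m_pairs
  lstm_model <- if (mode == "csp_lda") NULL else {
    stage("lstm", train_lstm_regressor(sequences, train$labels, lstm_cfg,
                                       classes))
  }
  f_lstm <- if (is.null(lstm_model)) rep(0, length(train)) else {
    vapply(sequences, function(s) lstm_forward(lstm_model, s), numeric(1L))
  }

  feat2 <- cbind(f_lda = f_lda, f_lstm = f_lstm)
  used <- switch(mode, fused = 1:2, csp_lda = 1L, lstm_only = 2L)
  mu <- colMeans(feat2[, used, drop = FALSE])
  sc <- apply(feat2[, used, drop = FALSE], 2L, stats::sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1
  Xs <- sweep(sweep(feat2[, used, drop = FALSE], 2L, mu), 2L, sc, `/`)
  gamma <- 1 / (2 * ncol(Xs) * mean(apply(Xs, 2L, stats::var)))
  svm_fit <- stage("svm", e1071::svm(
    Xs, factor(train$labels, levels = classes),
    kernel = "radial", cost = 1, gamma = gamma, scale = FALSE
  ))
  structure(
    list(csp_trial = csp_trial, csp_segment = csp_segment, lda = lda,
         lstm = lstm_model, svm = svm_fit, classes = classes,
         window = window, m_pairs = as.integer(m_pairs), mode = mode,
         feature_center = mu, feature_scale = sc, used_features = used,
         lstm_config = lstm_cfg, hyper = NULL,
         n_train = table(factor(train$labels, levels = classes))),
    class = "trained_optical_model"
  )
}

# Objective closure for Bayesian optimization: stratified inner-CV
# misclassification of the chosen scorer at candidate (learn_rate, l2).
make_hyper_objective <- function(train, m_pairs, window, lstm_cfg, classes,
                                 inner_folds, kind, mode, seed) {
  force(train)
  function(learn_rate, l2) {
    cfg <- lstm_cfg
    cfg$learn_rate <- learn_rate
    cfg$l2 <- l2
    folds <- stratified_folds(train$labels, inner_folds, seed)
    errs <- vapply(seq_len(inner_folds), function(k) {
      tr <- subset_trials(train, folds != k)
      te <- subset_trials(train, folds == k)
      if (kind == "optical") {
        m <- fit_optical_stages(tr, m_pairs, window, cfg, classes, mode)
        mean(predict_optical(m, te) != te$labels)
      } else {
        segs <- pool_segments(tr, window)
        bank <- learn_csp(segs, m_pairs, classes)
        seqs <- lapply(tr$trials, build_sequence_features,
                       p = window, bank = bank)
        cfg$input_dim <- 2L * bank$m_pairs
        lm <- train_lstm_regressor(seqs, tr$labels, cfg, classes)
        preds <- vapply(te$trials, function(E) {
          s <- build_sequence_features(E, window, bank)
          if (lstm_forward(lm, s) >= 0) classes[1L] else classes[2L]
        }, character(1L))
        mean(preds != te$labels)
      }
    }, numeric(1L))
    mean(errs)
  }
}

#' Extract the bivariate feature of a trial
#'
#' Runs both paths of the trained model on one (preprocessed) trial: the
#' whole-trial CSP + LDA scalar and the windowed-CSP + LSTM scalar, each
#' standardized with the training statistics.
#'
#' @param model a `trained_optical_model`.
#' @param trial channels x samples matrix (same layout as training data).
#' @return Named numeric vector `c(f_lda = ..., f_lstm = ...)` (raw scale),
#'   with attribute `"standardized"` holding the z-scored features the SVM
#'   consumes.
#' @export
extract_bivariate <- function(model, trial) {
  stopifnot(inherits(model, "trained_optical_model"), is.matrix(trial))
  f_lda <- project_lda(model$lda,
                       csp_features(apply_spatial_filter(model$csp_trial,
                                                         trial)))
  f_lstm <- if (is.null(model$lstm)) 0 else {
    lstm_feature(model$lstm,
                 build_sequence_features(trial, model$window,
                                         model$csp_segment))
  }
  raw <- c(f_lda = f_lda, f_lstm = f_lstm)
  std <- (raw[model$used_features] - model$feature_center) /
    model$feature_scale
  attr(raw, "standardized") <- std
  raw
}

#' Predict the class of one trial
#'
#' @param model a `trained_optical_model`.
#' @param trial channels x samples matrix.
#' @return One of the two training class labels.
#' @export
predict_trial <- function(model, trial) {
  f <- attr(extract_bivariate(model, trial), "standardized")
  x <- matrix(f, nrow = 1L)
  colnames(x) <- c("f_lda", "f_lstm")[model$used_features]
  as.character(predict(model$svm, x))
}

#' Predict the classes of every trial in a dataset
#'
#' @param model a `trained_optical_model`.
#' @param data an [epoched_dataset()].
#' @return Character vector of predicted labels.
#' @export
predict_optical <- function(model, data) {
  stopifnot(inherits(data, "epoched_dataset"))
  f <- vapply(data$trials,
              function(E) attr(extract_bivariate(model, E), "standardized"),
              numeric(length(model$used_features)))
  feats <- if (is.matrix(f)) t(f) else matrix(f, ncol = 1L)
  colnames(feats) <- c("f_lda", "f_lstm")[model$used_features]
  as.character(predict(model$svm, feats))
}

#' @export
print.trained_optical_model <- function(x, ...) {
  cat("<trained_optical_model> classes:", paste(x$classes, collapse = " vs "),
      " mode:", x$mode, "\n")
  cat("CSP: 2 x", ncol(x$csp_trial$W), "filters; window l =", x$window$l,
      ", t =", x$window$t, "\n")
  if (!is.null(x$hyper)) {
    cat("optimized learn_rate =", signif(x$hyper$best_learn_rate, 3),
        ", l2 =", signif(x$hyper$best_l2, 3), "\n")
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' Single-file archive of the fitted model object.
#'
#' @param model a `trained_optical_model` (or `cascade_model`).
#' @param path file path.
#' @return `read_optical_model` returns the model; `write_optical_model`
#'   returns `path` invisibly.
#' @export
write_optical_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_optical_model
#' @export
read_optical_model <- function(path) readRDS(path)
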