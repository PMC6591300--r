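# Independent step-by-step reference implementation of the gate equations
# (plain R loops over scalar vectors, no batching, no shared code).
reference_lstm <- function(model, seq) {
  sig <- function(x) 1 / (1 + exp(-x))
  x_t <- lapply(seq_len(nrow(seq)), function(t) seq[t, ])
  for (ly in model$layers) {
    H <- ly$H
    h <- rep(0, H); cc <- rep(0, H)
    out <- vector("list", length(x_t))
    for (t in seq_along(x_t)) {
      z <- drop(ly$Wx %*% x_t[[t]] + ly$Wh %*% h + ly$b)
      i_g <- sig(z[1:H])
      f_g <- sig(z[(H + 1):(2 * H)])
      g_g <- tanh(z[(2 * H + 1):(3 * H)])
      o_g <- sig(z[(3 * H + 1):(4 * H)])
      cc <- f_g * cc + i_g * g_g
      h <- o_g * tanh(cc)
      out[[t]] <- h
    }
    x_t <- out
  }
  sum(model$fc_w * x_t[[length(x_t)]]) + model$fc_b
}

toy_model <- function(input_dim = 3, hidden = c(2), seed = 21) {
  init_lstm(lstm_config(input_dim = input_dim, hidden_units = hidden,
                        init_seed = seed))
}

test_that("all-zero gate weights propagate the output bias", {
  m <- toy_model()
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$Wx[] <- 0; m$layers[[l]]$Wh[] <- 0; m$layers[[l]]$b[] <- 0
  }
  m$fc_w[] <- 0; m$fc_b <- 2.5
  set.seed(1)
  expect_equal(lstm_forward(m, matrix(rnorm(9), 3, 3)), 2.5)
  expect_equal(lstm_forward(m, matrix(rnorm(30), 10, 3)), 2.5)
})

test_that("the forward pass matches an independent gate-equation oracle", {
  set.seed(2)
  for (trial in 1:5) {
    m <- toy_model(hidden = c(2), seed = 30 + trial)
    s <- matrix(rnorm(9), 3, 3)
    expect_equal(lstm_forward(m, s), reference_lstm(m, s), tolerance = 1e-6)
  }
  # two stacked layers
  m2 <- toy_model(hidden = c(4, 2), seed = 40)
  s2 <- matrix(rnorm(15), 5, 3)
  expect_equal(lstm_forward(m2, s2), reference_lstm(m2, s2), tolerance = 1e-6)
  # pure function: identical input -> identical output
  expect_identical(lstm_forward(m2, s2), lstm_forward(m2, s2))
})

test_that("analytic gradients match finite differences on a toy model", {
  set.seed(3)
  m <- toy_model(input_dim = 2, hidden = c(2), seed = 50)
  seqs <- lapply(1:4, function(i) matrix(rnorm(6), 3, 2))
  targets <- c(0.5, -1, 0.25, 0.8)
  g <- lstm_loss_grad(m, seqs, targets)
  eps <- 1e-6
  perturb <- function(model, l, nm, idx, delta) {
    if (nm == "fc_w") model$fc_w[idx] <- model$fc_w[idx] + delta
    else if (nm == "fc_b") model$fc_b <- model$fc_b + delta
    else model$layers[[l]][[nm]][idx] <- model$layers[[l]][[nm]][idx] + delta
    model
  }
  checks <- list(
    list(1, "Wx", 1), list(1, "Wx", 7), list(1, "Wh", 3), list(1, "Wh", 14),
    list(1, "b", 2), list(1, "b", 6), list(NA, "fc_w", 1), list(NA, "fc_w", 2),
    list(NA, "fc_b", 1), list(1, "Wx", 12)
  )
  for (ck in checks) {
    l <- ck[[1]]; nm <- ck[[2]]; idx <- ck[[3]]
    lp <- lstm_loss_grad(perturb(m, l, nm, idx, eps), seqs, targets)$loss
    lm_ <- lstm_loss_grad(perturb(m, l, nm, idx, -eps), seqs, targets)$loss
    fd <- (lp - lm_) / (2 * eps)
    analytic <- if (nm == "fc_w") g$fc_w[idx]
      else if (nm == "fc_b") g$fc_b
      else g$layers[[l]][[nm]][idx]
    expect_equal(analytic, fd, tolerance = 1e-4)
  }
})

test_that("training fits constant targets and is deterministic", {
  set.seed(4)
  seqs <- lapply(1:12, function(i) matrix(rnorm(12), 4, 3))
  cfg <- lstm_config(input_dim = 3, hidden_units = c(8), max_epochs = 100,
                     learn_rate = 0.05, init_seed = 60)
  m <- train_lstm_regressor(seqs, config = cfg,
                            targets = rep(0.7, 12))
  preds <- vapply(seqs, function(s) lstm_forward(m, s), numeric(1))
  expect_true(all(abs(preds - 0.7) < 0.1))
  m2 <- train_lstm_regressor(seqs, config = cfg, targets = rep(0.7, 12))
  expect_identical(m$layers, m2$layers)
  expect_identical(m$training_curve, m2$training_curve)
  expect_length(m$training_curve, 100L)
  expect_true(all(is.finite(m$training_curve)))
})

test_that("training reduces the RMSE on separable sequences", {
  # class is encoded in the mean of feature 1
  set.seed(5)
  seqs <- lapply(1:40, function(i) {
    s <- matrix(rnorm(15, sd = 0.3), 5, 3)
    s[, 1] <- s[, 1] + if (i <= 20) 1 else -1
    s
  })
  labels <- rep(c("hi", "lo"), each = 20)
  cfg <- lstm_config(input_dim = 3, hidden_units = c(100, 20),
                     max_epochs = 100, init_seed = 61)
  m <- train_lstm_regressor(seqs, labels, cfg)
  expect_lt(m$training_curve[100], 0.5 * m$training_curve[1])
  expect_lte(tail(m$training_curve, 1), m$training_curve[1])
  # class-conditional ordering of the learned feature
  f <- vapply(seqs, function(s) lstm_feature(m, s), numeric(1))
  expect_gt(mean(f[labels == "hi"]), mean(f[labels == "lo"]))
  expect_true(all(is.finite(f)))
  # lstm_feature is definitionally lstm_forward
  expect_identical(lstm_feature(m, seqs[[1]]), lstm_forward(m, seqs[[1]]))
})

test_that("divergent learning rates raise a training error naming the rate", {
  set.seed(6)
  seqs <- lapply(1:8, function(i) matrix(rnorm(12, sd = 5), 4, 3))
  cfg <- lstm_config(input_dim = 3, hidden_units = c(4), learn_rate = 1e4,
                     max_epochs = 50, init_seed = 62)
  expect_error(train_lstm_regressor(seqs, config = cfg,
                                    targets = rep(c(1e6, -1e6), 4)),
               "diverged")
})

test_that("mismatched sequence shapes are rejected", {
  m <- toy_model()
  expect_error(lstm_forward(m, matrix(0, 3, 5)), "features")
  seqs <- list(matrix(0, 3, 3), matrix(0, 4, 3))
  expect_error(train_lstm_regressor(seqs, c("a", "b"),
                                    lstm_config(input_dim = 3)),
               "same length")
})
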