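# deterministic two-class trial factory with given per-channel scales
scaled_noise_trials <- function(n, scales, samples = 200, seed = 1) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    diag(scales) %*% matrix(rnorm(length(scales) * samples), length(scales))
  }))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

test_that("white-noise classes give eigenvalues near 1/2", {
  tr1 <- scaled_noise_trials(200, c(1, 1, 1, 1), seed = 2)
  tr2 <- scaled_noise_trials(200, c(1, 1, 1, 1), seed = 3)
  ds <- epoched_dataset(c(tr1, tr2), rep(c("a", "b"), each = 200), 100)
  bank <- learn_csp(ds, m_pairs = 2)
  expect_true(all(abs(bank$eigenvalues - 0.5) < 0.05))
})

test_that("the top CSP filter attains the brute-force optimal variance ratio", {
  # class covariances diag(9, 1) and diag(1, 9)
  tr1 <- scaled_noise_trials(200, c(3, 1), seed = 4)
  tr2 <- scaled_noise_trials(200, c(1, 3), seed = 5)
  ds <- epoched_dataset(c(tr1, tr2), rep(c("a", "b"), each = 200), 100)
  bank <- learn_csp(ds, m_pairs = 1)
  C1 <- opticalbci:::mean_normalized_cov(tr1)
  C2 <- opticalbci:::mean_normalized_cov(tr2)
  ratio <- function(w) drop(crossprod(w, C1 %*% w) / crossprod(w, C2 %*% w))
  # brute-force direction grid oracle
  th <- seq(0, pi, length.out = 3600)
  grid_best <- max(vapply(th, function(a) ratio(c(cos(a), sin(a))), numeric(1)))
  achieved <- ratio(bank$W[, 1])
  expect_gt(achieved, grid_best * 0.99)
})

test_that("the full eigenbasis whitens the composite covariance", {
  ds <- small_preprocessed(n_trials_per_class = 20)
  bank <- suppressWarnings(learn_csp(ds))
  expect_identical(dim(bank$W), c(8L, 6L))
  cls <- unique(ds$labels)
  C1 <- opticalbci:::mean_normalized_cov(ds$trials[ds$labels == cls[1]])
  C2 <- opticalbci:::mean_normalized_cov(ds$trials[ds$labels == cls[2]])
  G <- crossprod(bank$W_full, (C1 + C2) %*% bank$W_full)
  expect_lt(max(abs(G - diag(ncol(bank$W_full)))), 1e-8)
})

test_that("eigenvalues are complementary between the two class problems", {
  tr1 <- scaled_noise_trials(100, c(2, 1, 1.5, 0.7), seed = 6)
  tr2 <- scaled_noise_trials(100, c(1, 2, 0.7, 1.5), seed = 7)
  ds <- epoched_dataset(c(tr1, tr2), rep(c("a", "b"), each = 100), 100)
  b12 <- learn_csp(ds, m_pairs = 2, classes = c("a", "b"))
  b21 <- learn_csp(ds, m_pairs = 2, classes = c("b", "a"))
  expect_equal(sort(b12$eigenvalues) + rev(sort(b21$eigenvalues)),
               rep(1, 4), tolerance = 1e-8)
})

test_that("filters are invariant to a global amplitude rescaling", {
  ds <- small_preprocessed(n_trials_per_class = 10)
  scaled <- ds
  scaled$trials <- lapply(ds$trials, function(t) 37.5 * t)
  b1 <- suppressWarnings(learn_csp(ds))
  b2 <- suppressWarnings(learn_csp(scaled))
  cosines <- abs(colSums(b1$W * b2$W)) /
    (sqrt(colSums(b1$W^2)) * sqrt(colSums(b2$W^2)))
  expect_true(all(cosines > 1 - 1e-8))
})

test_that("the top filter recovers the true unmixing direction on synthetic data", {
  cfg <- small_config(n_trials_per_class = 200, snr = 25)
  ds <- suppressWarnings(preprocess(generate_mi_dataset(cfg)))
  A <- attr(generate_mi_dataset(cfg), "mixing")
  bank <- suppressWarnings(learn_csp(ds, classes = c("left", "right")))
  # true unmixing direction for source 1 (orthogonal mixing): column 1 of A
  w <- bank$W[, 1]
  u <- A[, 1]
  cosine <- abs(sum(w * u)) / sqrt(sum(w^2) * sum(u^2))
  expect_gt(cosine, 0.9)
})

test_that("spatial filtering is the exact matrix product", {
  set.seed(8)
  E <- matrix(rnorm(8 * 200), 8)
  # identity bank returns the trial unchanged
  expect_equal(apply_spatial_filter(diag(8), E), E, ignore_attr = TRUE)
  W <- matrix(rnorm(8 * 6), 8, 6)
  Z <- apply_spatial_filter(W, E)
  expect_identical(dim(Z), c(6L, 200L))
  # naive triple-loop oracle
  Zo <- matrix(0, 6, 200)
  for (i in 1:6) for (j in 1:200) {
    acc <- 0
    for (k in 1:8) acc <- acc + W[k, i] * E[k, j]
    Zo[i, j] <- acc
  }
  expect_equal(Z, Zo, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_spatial_filter(W, E[1:4, ]), "channels")
})

test_that("log-variance features use the n-1 sample variance with flooring", {
  z <- matrix(rep(c(1, -1), 50), 1)      # n = 100 alternating
  y <- csp_features(z)
  expect_equal(y, log(100 / 99), tolerance = 1e-12)
  expect_warning(yc <- csp_features(matrix(5, 2, 50)), "floored")
  expect_equal(yc, rep(log(1e-12), 2))
  set.seed(9)
  r <- rnorm(501)
  # two-pass variance oracle
  v2 <- sum((r - mean(r))^2) / 500
  expect_equal(csp_features(matrix(r, 1)), log(v2), tolerance = 1e-10)
})

test_that("one-vs-rest CSP equals two-class CSP on the relabeled problem", {
  cfg <- small_config(n_trials_per_class = 15)
  mi <- generate_mi_dataset(cfg)
  nt <- generate_nontask_trials(cfg)
  all3 <- bind_datasets(mi, nt)
  ovr <- suppressWarnings(learn_csp_ovr(all3, "nontask"))
  manual <- all3
  manual$labels <- ifelse(all3$labels == "nontask", "nontask", ".rest")
  direct <- suppressWarnings(learn_csp(manual, classes = c("nontask", ".rest")))
  expect_equal(ovr$W, direct$W)
  # k = 2 reduces to plain CSP
  ovr2 <- suppressWarnings(learn_csp_ovr(mi, "left"))
  plain <- suppressWarnings(learn_csp(mi, classes = c("left", "right")))
  expect_equal(ovr2$W, plain$W)
  # different targets give different filters
  ovr_l <- suppressWarnings(learn_csp_ovr(all3, "left"))
  expect_gt(max(abs(ovr$W - ovr_l$W)), 1e-3)
})

test_that("degenerate CSP inputs raise errors", {
  tr <- scaled_noise_trials(4, c(1, 1), seed = 10)
  one_class <- epoched_dataset(tr, rep("a", 4), 100)
  expect_error(learn_csp(one_class), "two classes")
  ds <- epoched_dataset(tr, c("a", "a", "b", "b"), 100)
  expect_error(learn_csp(ds, m_pairs = 3), "channels")
})
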