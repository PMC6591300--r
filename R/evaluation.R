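#' Performance measures from confusion counts
#'
#' Computes, from two-class confusion counts: misclassification rate
#' `(FP + FN) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, and Cohen's kappa `(p_a - p_e) / (1 - p_e)` with
#' observed agreement `p_a = (TP + TN) / total` and chance agreement `p_e`
#' from the products of the marginals. A metric whose margin is empty is
#' returned as `NA`.
#'
#' @param tp,tn,fp,fn non-negative trial counts.
#' @return A one-row [tibble::tibble()] with columns `misclassification`,
#'   `sensitivity`, `specificity`, `kappa`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total")
  }
  total <- sum(counts)
  mis <- (fp + fn) / total
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  p_a <- (tp + tn) / total
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  kappa <- if (abs(1 - p_e) < 1e-15) NA_real_ else (p_a - p_e) / (1 - p_e)
  tibble::tibble(misclassification = mis, sensitivity = sens,
                 specificity = spec, kappa = kappa)
}

# Seeded stratified fold assignment: within each class, a shuffled
# round-robin over folds 1..k.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop("class '", cl, "' has ", length(idx),
             " trials, fewer than k = ", k)
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `reps` independent repetitions of seeded stratified k-fold CV. All
#' model fitting happens inside the training folds only; each trial is
#' tested exactly once per repetition. Fold scores are averaged (not
#' count-pooled) into the aggregate.
#'
#' @param data an [epoched_dataset()].
#' @param trainer function `(train_dataset, fold_seed) -> model`.
#' @param predictor function `(model, test_dataset) -> character labels`;
#'   defaults to [predict_optical()].
#' @param k folds (default 10).
#' @param reps repetitions (default 10).
#' @param seed base seed; repetition r uses `seed + r` for its partition.
#' @param positive_class class counted as positive in Eqs for sensitivity /
#'   specificity; defaults to the first class in dataset order. With more
#'   than two classes only the misclassification rate is reported.
#' @return A `performance_report`: list with `per_fold` (tibble: repetition,
#'   fold, misclassification, sensitivity, specificity, kappa), `aggregate`
#'   (tibble of means and SDs over all `k * reps` folds), and
#'   `positive_class`.
#' @export
cross_validate <- function(data, trainer, predictor = predict_optical,
                           k = 10, reps = 10, seed = 1,
                           positive_class = NULL) {
  stopifnot(inherits(data, "epoched_dataset"))
  classes <- unique(data$labels)
  two_class <- length(classes) == 2L
  if (is.null(positive_class)) positive_class <- classes[1L]
  rows <- vector("list", k * reps)
  n <- 0L
  for (r in seq_len(reps)) {
    folds <- stratified_folds(data$labels, k, seed + r)
    for (f in seq_len(k)) {
      tr <- subset_trials(data, folds != f)
      te <- subset_trials(data, folds == f)
      model <- trainer(tr, seed * 1000L + r * 100L + f)
      pred <- predictor(model, te)
      truth <- te$labels
      if (two_class) {
        tp <- sum(pred == positive_class & truth == positive_class)
        tn <- sum(pred != positive_class & truth != positive_class)
        fp <- sum(pred == positive_class & truth != positive_class)
        fn <- sum(pred != positive_class & truth == positive_class)
        m <- compute_metrics(tp, tn, fp, fn)
      } else {
        m <- tibble::tibble(misclassification = mean(pred != truth),
                            sensitivity = NA_real_, specificity = NA_real_,
                            kappa = NA_real_)
      }
      n <- n + 1L
      rows[[n]] <- tibble::tibble(repetition = r, fold = f, m)
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- tibble::tibble(
    metric = c("misclassification", "sensitivity", "specificity", "kappa"),
    mean = unname(vapply(per_fold[, 3:6], mean, numeric(1L), na.rm = TRUE)),
    sd = unname(vapply(per_fold[, 3:6], stats::sd, numeric(1L), na.rm = TRUE))
  )
  structure(list(per_fold = per_fold, aggregate = agg,
                 positive_class = positive_class,
                 k = k, reps = reps, seed = seed),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> ", x$reps, " x ", x$k, "-fold CV, positive class '",
      x$positive_class, "'\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' Per-fold results of a performance report
#'
#' @param x a `performance_report`.
#' @param ... unused.
#' @return The per-fold tibble (one row per repetition x fold).
#' @export
tidy.performance_report <- function(x, ...) x$per_fold

#' One-row summary of a performance report
#'
#' @param x a `performance_report`.
#' @param ... unused.
#' @return A one-row tibble of aggregate means and SDs.
#' @export
glance.performance_report <- function(x, ...) {
  out <- as.list(x$aggregate$mean)
  names(out) <- x$aggregate$metric
  sds <- as.list(x$aggregate$sd)
  names(sds) <- paste0(x$aggregate$metric, "_sd")
  tibble::as_tibble(c(out, sds))
}

#' Write a performance report to CSV
#'
#' Per-fold rows followed by one aggregate row per metric; a comment header
#' records the CV layout and seed.
#'
#' @param report a `performance_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d x %d-fold CV, seed %d, positive class %s",
                     report$reps, report$k, report$seed,
                     report$positive_class), con)
  utils::write.csv(report$per_fold, con, row.names = FALSE)
  writeLines("# aggregate (mean, sd over folds)", con)
  utils::write.csv(report$aggregate, con, row.names = FALSE)
  invisible(path)
}

#' Paired t-test on per-subject rates
#'
#' Classical paired t statistic on the differences `a - b`, with a two-sided
#' p-value from the t distribution with `n - 1` degrees of freedom.
#'
#' @param rates_a,rates_b numeric vectors of equal length (>= 2), e.g.
#'   per-subject misclassification rates of two methods.
#' @return A one-row tibble with `t`, `df`, `p_value`.
#' @export
paired_ttest <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b) || length(rates_a) < 2L) {
    stop("inputs must have equal length >= 2")
  }
  d <- rates_a - rates_b
  if (stats::sd(d) < 1e-15) {
    stop("degenerate paired differences (zero variance)")
  }
  ht <- stats::t.test(rates_a, rates_b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}
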