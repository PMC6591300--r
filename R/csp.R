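#' Learn common spatial pattern (CSP) filters
#'
#' Estimates spatial filters that maximize the variance of one class while
#' minimizing the variance of the other. Each trial `E` contributes a
#' trace-normalized covariance `C = E E^T / trace(E E^T)`; the class-mean
#' covariances `C1`, `C2` enter the generalized eigenproblem
#' `C1 w = lambda (C1 + C2) w`. With eigenvalues sorted descending, the
#' filter bank keeps the `m_pairs` leading and `m_pairs` trailing
#' eigenvectors (largest variance ratio for each class).
#'
#' @param data an [epoched_dataset()] restricted to exactly two classes.
#' @param m_pairs number of filter pairs kept (default 3, i.e. six filters).
#' @param classes optional length-2 character vector fixing class order;
#'   the first entry is the "positive" class whose variance the leading
#'   filters maximize.
#' @return A `spatial_filter_bank`: list with `W` (channels x 2*m_pairs),
#'   `eigenvalues` (for the kept columns, in (0,1)), `positive_class`,
#'   `m_pairs`, and `W_full` (the complete eigenbasis, satisfying
#'   `t(W_full) %*% (C1 + C2) %*% W_full = I`).
#' @export
learn_csp <- function(data, m_pairs = 3, classes = NULL) {
  stopifnot(inherits(data, "epoched_dataset"))
  if (is.null(classes)) classes <- unique(data$labels)
  if (length(classes) != 2L) {
    stop("CSP needs exactly two classes, got: ",
         paste(unique(data$labels), collapse = ", "))
  }
  n_ch <- nrow(data$trials[[1L]])
  if (n_ch < 2L * m_pairs) {
    stop("need at least 2 * m_pairs = ", 2L * m_pairs, " channels")
  }
  for (cl in classes) {
    if (sum(data$labels == cl) < 2L) {
      stop("class '", cl, "' has fewer than 2 trials")
    }
  }
  C1 <- mean_normalized_cov(data$trials[data$labels == classes[1L]])
  C2 <- mean_normalized_cov(data$trials[data$labels == classes[2L]])
  csp_from_covariances(C1, C2, m_pairs, positive_class = classes[1L])
}

mean_normalized_cov <- function(trials) {
  covs <- lapply(trials, function(E) {
    C <- tcrossprod(E)
    C / sum(diag(C))
  })
  Reduce(`+`, covs) / length(covs)
}

# Solve C1 w = lambda (C1 + C2) w by whitening; lambda in (0,1).
# A rank-deficient composite covariance (the constant direction after common
# average referencing, always) is handled by whitening in its principal
# subspace: null directions carry no variance in either class, so no
# discriminative filter can live there.
csp_from_covariances <- function(C1, C2, m_pairs, positive_class) {
  Cc <- C1 + C2
  n_ch <- nrow(Cc)
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- 1e-10 * max(ec$values)
  keep <- ec$values > tol
  if (!all(keep)) {
    warning("composite covariance is rank-deficient (rank ", sum(keep),
            " of ", n_ch, "); whitening in its principal subspace")
    if (sum(keep) < 2L * m_pairs) {
      stop("covariance rank ", sum(keep), " is below 2 * m_pairs = ",
           2L * m_pairs)
    }
  }
  P <- diag(1 / sqrt(ec$values[keep]), sum(keep)) %*%
    t(ec$vectors[, keep, drop = FALSE])                # P Cc P^T = I (rank r)
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  es <- eigen(S1, symmetric = TRUE)                    # eigenvalues descending
  W_full <- t(P) %*% es$vectors
  # sign convention: largest-magnitude component of each column positive
  for (j in seq_len(ncol(W_full))) {
    k <- which.max(abs(W_full[, j]))
    if (W_full[k, j] < 0) W_full[, j] <- -W_full[, j]
  }
  r <- ncol(W_full)
  keep <- c(seq_len(m_pairs), seq(r - m_pairs + 1L, r))
  structure(
    list(W = W_full[, keep, drop = FALSE],
         eigenvalues = es$values[keep],
         positive_class = positive_class,
         m_pairs = as.integer(m_pairs),
         W_full = W_full),
    class = "spatial_filter_bank"
  )
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("<spatial_filter_bank> ", nrow(x$W), " channels -> ", ncol(x$W),
      " filters (m_pairs = ", x$m_pairs, "), positive class '",
      x$positive_class, "'\n", sep = "")
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Learn one-vs-rest CSP filters
#'
#' Pools every trial not belonging to `target_class` into a single "rest"
#' class and runs two-class CSP with the target as the positive class.
#'
#' @param data an [epoched_dataset()] with two or more classes.
#' @param target_class the class whose variance the leading filters maximize.
#' @param m_pairs number of filter pairs (default 3).
#' @return A `spatial_filter_bank` (see [learn_csp()]).
#' @export
learn_csp_ovr <- function(data, target_class, m_pairs = 3) {
  stopifnot(inherits(data, "epoched_dataset"))
  if (!target_class %in% data$labels) {
    stop("target class '", target_class, "' not present")
  }
  relabeled <- data
  relabeled$labels <- ifelse(data$labels == target_class,
                             target_class, ".rest")
  learn_csp(relabeled, m_pairs = m_pairs,
            classes = c(target_class, ".rest"))
}

#' Spatially filter a trial
#'
#' Computes `Z = W^T E`.
#'
#' @param bank a `spatial_filter_bank` from [learn_csp()], or a plain
#'   weight matrix `W` (channels x filters).
#' @param E channels x samples trial matrix.
#' @return The filtered signal `Z` (filters x samples).
#' @export
apply_spatial_filter <- function(bank, E) {
  W <- if (inherits(bank, "spatial_filter_bank")) bank$W else bank
  stopifnot(is.matrix(W), is.matrix(E))
  if (nrow(W) != nrow(E)) {
    stop("filter bank expects ", nrow(W), " channels, trial has ", nrow(E))
  }
  crossprod(W, E)
}

#' CSP log-variance features
#'
#' Computes `y_i = log(var(Z_i))` for each row of the spatially filtered
#' signal, with sample variance (divisor n - 1). Variances below 1e-12 are
#' floored (with a warning) so the log stays finite.
#'
#' @param Z filters x samples matrix from [apply_spatial_filter()].
#' @return Numeric vector of log-variance features, one per row of `Z`.
#' @export
csp_features <- function(Z) {
  stopifnot(is.matrix(Z), ncol(Z) >= 2L)
  v <- apply(Z, 1L, stats::var)
  if (any(v < 1e-12)) {
    warning("variance floored at 1e-12 for ", sum(v < 1e-12), " filter(s)")
    v <- pmax(v, 1e-12)
  }
  log(v)
}

#' Whole-dataset CSP feature matrix
#'
#' @param bank a `spatial_filter_bank`.
#' @param data an [epoched_dataset()].
#' @return A trials x filters numeric matrix of log-variance features.
#' @export
csp_feature_matrix <- function(bank, data) {
  stopifnot(inherits(data, "epoched_dataset"))
  t(vapply(data$trials,
           function(E) csp_features(apply_spatial_filter(bank, E)),
           numeric(ncol(if (inherits(bank, "spatial_filter_bank")) bank$W
                        else bank))))
}
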