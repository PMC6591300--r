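#' Fit a Fisher linear discriminant projection
#'
#' Reduces d-dimensional feature vectors to one scalar. The direction is
#' `w ~ Sw^-1 (mu1 - mu2)` with pooled within-class scatter `Sw`
#' (shrinkage-regularized towards its diagonal when ill-conditioned),
#' normalized to unit length with the sign fixed so that the projected mean
#' of the first class exceeds that of the second; the offset centers the
#' projection at the midpoint of the class means.
#'
#' @param x n x d numeric feature matrix.
#' @param labels class id per row; exactly two classes, each with >= 2 rows.
#' @param classes optional length-2 vector fixing which class is first
#'   (projected high).
#' @return An `lda_projection`: list with unit vector `w`, offset `b`,
#'   `classes`, and `class_means_projected`.
#' @export
fit_lda <- function(x, labels, classes = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  if (length(classes) != 2L) stop("LDA needs exactly two classes")
  i1 <- labels == classes[1L]
  i2 <- labels == classes[2L]
  if (sum(i1) < 2L || sum(i2) < 2L) stop("need >= 2 samples per class")
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[i2, , drop = FALSE])
  delta <- mu1 - mu2
  if (sqrt(sum(delta^2)) < 1e-12) {
    stop("degenerate separation: identical class means")
  }
  n1 <- sum(i1); n2 <- sum(i2)
  S1 <- stats::cov(x[i1, , drop = FALSE])
  S2 <- stats::cov(x[i2, , drop = FALSE])
  Sw <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  Sw <- shrink_if_ill_conditioned(Sw)
  w <- solve(Sw, delta)
  w <- w / sqrt(sum(w^2))
  if (sum(w * delta) < 0) w <- -w
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(
    list(w = w, b = b, classes = classes,
         class_means_projected = c(sum(w * mu1) + b, sum(w * mu2) + b)),
    class = "lda_projection"
  )
}

# Shrink towards the diagonal until the condition number is workable; the
# whole-trial CSP features are only 6-dimensional but training folds are
# small (~180 trials), so near-singular scatter can occur.
shrink_if_ill_conditioned <- function(Sw, cond_max = 1e8) {
  d <- nrow(Sw)
  target <- diag(diag(Sw), d)
  gamma <- 0
  repeat {
    S <- (1 - gamma) * Sw + gamma * target
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) <= cond_max) return(S)
    gamma <- if (gamma == 0) 1e-4 else gamma * 10
    if (gamma >= 1) {
      # fully diagonal and still degenerate: ridge as a last resort
      return(target + diag(1e-8 * max(diag(Sw), 1e-12), d))
    }
  }
}

#' Project features with a fitted LDA
#'
#' @param p an `lda_projection` from [fit_lda()].
#' @param x a d-vector or an n x d matrix.
#' @return Scalar (or length-n vector) `w . x + b`.
#' @export
project_lda <- function(p, x) {
  stopifnot(inherits(p, "lda_projection"))
  if (is.matrix(x)) {
    if (ncol(x) != length(p$w)) stop("feature dimension mismatch")
    return(drop(x %*% p$w) + p$b)
  }
  if (length(x) != length(p$w)) stop("feature dimension mismatch")
  sum(p$w * x) + p$b
}

#' @export
print.lda_projection <- function(x, ...) {
  cat("<lda_projection> d =", length(x$w), " classes:",
      paste(x$classes, collapse = " vs "), "\n")
  invisible(x)
}
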