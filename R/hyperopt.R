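#' Hyper-parameter search box
#'
#' The search region for the LSTM's initial learn rate and L2 penalty,
#' defaulting to the intervals [1e-4, 1e-1] and [1e-5, 1e-3]; both are
#' searched on a log10 scale since they span three decades.
#'
#' @param learn_rate_range,l2_range positive intervals (lower, upper).
#' @param budget number of objective evaluations.
#' @param seed seed for the initial design and candidate draws.
#' @return A `hyper_box` list.
#' @export
hyper_box <- function(learn_rate_range = c(1e-4, 1e-1),
                      l2_range = c(1e-5, 1e-3),
                      budget = 30, seed = 1) {
  for (r in list(learn_rate_range, l2_range)) {
    if (length(r) != 2L || r[1L] <= 0 || r[1L] >= r[2L]) {
      stop("ranges must be positive with lower < upper")
    }
  }
  if (budget < 5) stop("budget must be >= 5")
  structure(list(learn_rate_range = learn_rate_range, l2_range = l2_range,
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "hyper_box")
}

# Squared-exponential kernel on the unit box
gp_kernel <- function(X1, X2, ell, sf2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  sf2 * exp(-pmax(d2, 0) / (2 * ell^2))
}

# Fit a zero-mean GP to standardized observations; lengthscale chosen by
# marginal likelihood over a small grid.
gp_fit <- function(X, y) {
  mu <- mean(y); sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  ys <- (y - mu) / sdv
  n <- length(ys)
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.3, 0.5, 1)) {
    K <- gp_kernel(X, X, ell, 1) + diag(1e-6, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
    if (is.null(best) || ll > best$ll) {
      best <- list(ell = ell, ch = ch, alpha = alpha, ll = ll)
    }
  }
  c(best, list(X = X, mu = mu, sdv = sdv))
}

gp_predict <- function(fit, Xs) {
  Ks <- gp_kernel(Xs, fit$X, fit$ell, 1)
  mean_s <- drop(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$ch), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdv * mean_s,
       sd = fit$sdv * sqrt(var_s))
}

expected_improvement <- function(mean_s, sd_s, best_y) {
  z <- (best_y - mean_s) / sd_s
  (best_y - mean_s) * stats::pnorm(z) + sd_s * stats::dnorm(z)
}

#' Bayesian optimization of the LSTM hyper-parameters
#'
#' Minimizes `objective(learn_rate, l2)` (typically a cross-validated
#' misclassification rate, in [0, 1]) over the box using a Gaussian-process
#' surrogate on the log10-transformed parameters and the expected-improvement
#' acquisition, spending exactly `box$budget` evaluations (a seeded
#' Latin-hypercube initial design followed by EI-chosen points).
#'
#' @param objective a function `(learn_rate, l2) -> numeric scalar`.
#' @param box a [hyper_box()].
#' @param n_initial size of the initial space-filling design (default 5).
#' @return A `hyper_result`: list with `best_learn_rate`, `best_l2`,
#'   `best_objective`, and `trace` (a tibble with one row per evaluation:
#'   `iter`, `learn_rate`, `l2`, `objective`, `best_so_far`).
#' @export
bayes_optimize <- function(objective, box = hyper_box(), n_initial = 5) {
  stopifnot(inherits(box, "hyper_box"), is.function(objective))
  lo <- log10(c(box$learn_rate_range[1L], box$l2_range[1L]))
  hi <- log10(c(box$learn_rate_range[2L], box$l2_range[2L]))
  to_params <- function(u) 10^(lo + u * (hi - lo))     # unit box -> params
  n_initial <- min(n_initial, box$budget)
  evals_u <- matrix(0, 0, 2L)
  evals_y <- numeric(0)
  trace <- vector("list", box$budget)
  with_seed(box$seed, {
    U0 <- lhs::randomLHS(n_initial, 2L)
    for (k in seq_len(box$budget)) {
      if (k <= n_initial) {
        u <- U0[k, ]
      } else {
        ok <- is.finite(evals_y)
        if (sum(ok) >= 2L) {
          fit <- gp_fit(evals_u[ok, , drop = FALSE], evals_y[ok])
          cand <- matrix(stats::runif(2000), ncol = 2L)
          pr <- gp_predict(fit, cand)
          ei <- expected_improvement(pr$mean, pr$sd, min(evals_y[ok]))
          u <- cand[which.max(ei), ]
        } else {
          u <- stats::runif(2L)
        }
      }
      p <- to_params(u)
      y <- tryCatch(objective(p[1L], p[2L]), error = function(e) NA_real_)
      evals_u <- rbind(evals_u, u)
      evals_y <- c(evals_y, y)
      trace[[k]] <- tibble::tibble(
        iter = k, learn_rate = p[1L], l2 = p[2L], objective = y,
        best_so_far = suppressWarnings(min(evals_y, na.rm = TRUE))
      )
    }
  })
  if (all(!is.finite(evals_y))) {
    stop("optimization failed: the objective errored on every evaluation")
  }
  trace <- do.call(rbind, trace)
  best <- which.min(evals_y)
  bp <- to_params(evals_u[best, ])
  structure(
    list(best_learn_rate = bp[1L], best_l2 = bp[2L],
         best_objective = evals_y[best], trace = trace),
    class = "hyper_result"
  )
}

#' @export
print.hyper_result <- function(x, ...) {
  cat("<hyper_result> best learn_rate =", signif(x$best_learn_rate, 4),
      ", best l2 =", signif(x$best_l2, 4),
      ", objective =", signif(x$best_objective, 4), "\n")
  invisible(x)
}
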