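#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot per-fold cross-validation scores
#'
#' Box plots of the per-fold misclassification, sensitivity, specificity and
#' kappa across all repetitions.
#'
#' @param object a `performance_report` from [cross_validate()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.performance_report <- function(object, ...) {
  pf <- object$per_fold
  long <- do.call(rbind, lapply(
    c("misclassification", "sensitivity", "specificity", "kappa"),
    function(m) tibble::tibble(metric = m, value = pf[[m]])
  ))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "per-fold score",
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$reps, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a Bayesian-optimization trace
#'
#' Objective value per evaluation with the running incumbent.
#'
#' @param object a `hyper_result` from [bayes_optimize()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hyper_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iter)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far),
                       color = "steelblue") +
    ggplot2::labs(x = "evaluation", y = "objective",
                  title = "Bayesian optimization trace") +
    ggplot2::theme_minimal()
}

#' Plot the LSTM training curve
#'
#' Root-mean-squared training error per epoch.
#'
#' @param object a trained `lstm_regressor`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lstm_regressor <- function(object, ...) {
  stopifnot(length(object$training_curve) > 0)
  df <- tibble::tibble(epoch = seq_along(object$training_curve),
                       rmse = object$training_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training RMSE",
                  title = "LSTM training curve") +
    ggplot2::theme_minimal()
}
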