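#' Balance non-task trials against the MI trials
#'
#' Draws a uniform random subsample of the non-task trials whose size equals
#' the total number of MI trials, avoiding class imbalance in the first
#' cascade stage. If fewer non-task trials exist, all are kept with a
#' warning.
#'
#' @param mi an [epoched_dataset()] of MI trials.
#' @param nontask an [epoched_dataset()] of non-task trials.
#' @param seed seed for the subsample draw.
#' @return An [epoched_dataset()] of the selected non-task trials.
#' @export
balance_non_task <- function(mi, nontask, seed = 1) {
  stopifnot(inherits(mi, "epoched_dataset"),
            inherits(nontask, "epoched_dataset"))
  if (length(mi) == 0L || length(nontask) == 0L) {
    stop("both datasets must be non-empty")
  }
  n_mi <- length(mi)
  if (length(nontask) < n_mi) {
    warning("only ", length(nontask), " non-task trials available for ",
            n_mi, " MI trials; keeping all")
    return(nontask)
  }
  idx <- with_seed(seed, sample.int(length(nontask), n_mi))
  subset_trials(nontask, sort(idx))
}

#' Train the two-stage one-vs-rest cascade
#'
#' Stage 1 discriminates non-task activity from (pooled) MI activity using
#' a balanced non-task subsample; stage 2 discriminates the two MI classes
#' and is trained on MI trials only. Each stage is a full
#' `trained_optical_model` with its own spatial filters.
#'
#' @param mi an [epoched_dataset()] with the two MI classes.
#' @param nontask an [epoched_dataset()] of non-task trials.
#' @param seed seed (balancing draw and both stage fits).
#' @param ... passed to [train_optical()] for both stages.
#' @return A `cascade_model`: list with `stage1`, `stage2`, `labels`,
#'   `mi_label` (the pooled-MI pseudo-label used by stage 1), and
#'   `stage2_train_labels` (audit record of what stage 2 saw).
#' @export
train_cascade <- function(mi, nontask, seed = 1, ...) {
  stopifnot(inherits(mi, "epoched_dataset"),
            inherits(nontask, "epoched_dataset"))
  mi_classes <- unique(mi$labels)
  if (length(mi_classes) != 2L) stop("MI dataset must have exactly 2 classes")
  nt_label <- unique(nontask$labels)
  if (length(nt_label) != 1L) stop("non-task dataset must have one class")
  bal <- balance_non_task(mi, nontask, seed)
  pooled <- mi
  pooled$labels <- rep(".mi", length(mi))
  stage1_train <- bind_datasets(bal, pooled)
  stage1 <- train_optical(stage1_train, seed = seed, ...)
  stage2 <- train_optical(mi, seed = seed + 1L, ...)
  structure(
    list(stage1 = stage1, stage2 = stage2,
         labels = c(nt_label, mi_classes), mi_label = ".mi",
         nontask_label = nt_label,
         stage2_train_labels = mi$labels),
    class = "cascade_model"
  )
}

#' Predict with the cascade
#'
#' Stage 1 decides non-task vs MI; only trials called MI reach stage 2,
#' which assigns the final left/right label.
#'
#' @param model a `cascade_model`.
#' @param trial channels x samples matrix.
#' @return One of the three class labels.
#' @export
predict_cascade <- function(model, trial) {
  stopifnot(inherits(model, "cascade_model"))
  s1 <- predict_trial(model$stage1, trial)
  if (s1 == model$nontask_label) return(s1)
  predict_trial(model$stage2, trial)
}

#' Predict every trial of a dataset with the cascade
#'
#' @param model a `cascade_model`.
#' @param data an [epoched_dataset()].
#' @param stage1_oracle optional character vector of stage-1 decisions (one
#'   of `model$nontask_label` or anything else, per trial) substituted for
#'   the stage-1 classifier — used for compositional audits.
#' @return Character vector of 3-class labels.
#' @export
predict_cascade_dataset <- function(model, data, stage1_oracle = NULL) {
  stopifnot(inherits(model, "cascade_model"),
            inherits(data, "epoched_dataset"))
  s1 <- if (is.null(stage1_oracle)) {
    vapply(data$trials, function(E) predict_trial(model$stage1, E),
           character(1L))
  } else {
    stopifnot(length(stage1_oracle) == length(data))
    as.character(stage1_oracle)
  }
  out <- s1
  mi_idx <- which(s1 != model$nontask_label)
  if (length(mi_idx)) {
    out[mi_idx] <- predict_optical(model$stage2, subset_trials(data, mi_idx))
  }
  out
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("<cascade_model> stage 1: '", x$nontask_label, "' vs pooled MI; ",
      "stage 2: ", paste(x$stage2$classes, collapse = " vs "), "\n", sep = "")
  invisible(x)
}
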