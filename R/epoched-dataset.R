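#' Epoched EEG dataset
#'
#' Container for a set of equally shaped EEG trials. Each trial is a numeric
#' `channels x samples` matrix (microvolts); `labels` holds one class id per
#' trial.
#'
#' @param trials list of numeric matrices, all `channels x samples` with the
#'   same dimensions.
#' @param labels character vector of class ids, one per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel names; defaults
#'   to `"C1"`, `"C2"`, ...
#'
#' @return An object of class `epoched_dataset`: a list with elements
#'   `trials`, `labels`, `fs`, `channel_names`.
#' @export
epoched_dataset <- function(trials, labels, fs, channel_names = NULL) {
  if (!is.list(trials) || length(trials) == 0L) {
    stop("`trials` must be a non-empty list of matrices")
  }
  dims <- dim(trials[[1L]])
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (!is.matrix(tr) || !is.numeric(tr)) {
      stop("trial ", i, " is not a numeric matrix")
    }
    if (!identical(dim(tr), dims)) {
      stop("trial ", i, " has dimensions ", paste(dim(tr), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"))
    }
  }
  labels <- as.character(labels)
  if (length(labels) != length(trials)) {
    stop("`labels` length (", length(labels), ") != number of trials (",
         length(trials), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (is.null(channel_names)) channel_names <- paste0("C", seq_len(dims[1L]))
  if (length(channel_names) != dims[1L]) {
    stop("`channel_names` length != number of channels")
  }
  structure(
    list(trials = trials, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "epoched_dataset"
  )
}

#' @export
print.epoched_dataset <- function(x, ...) {
  dims <- dim(x$trials[[1L]])
  cat("<epoched_dataset> ", length(x$trials), " trials, ",
      dims[1L], " channels x ", dims[2L], " samples @ ", x$fs, " Hz\n",
      sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
length.epoched_dataset <- function(x) length(x$trials)

#' Subset an epoched dataset by trial index
#'
#' @param data an [epoched_dataset()].
#' @param idx integer or logical trial index.
#' @return An `epoched_dataset` holding the selected trials.
#' @export
subset_trials <- function(data, idx) {
  stopifnot(inherits(data, "epoched_dataset"))
  epoched_dataset(data$trials[idx], data$labels[idx], data$fs,
                  data$channel_names)
}

#' Concatenate epoched datasets
#'
#' @param ... `epoched_dataset` objects sharing channel layout and fs.
#' @return A single `epoched_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  fs <- parts[[1L]]$fs
  chn <- parts[[1L]]$channel_names
  for (p in parts) {
    stopifnot(inherits(p, "epoched_dataset"))
    if (!isTRUE(all.equal(p$fs, fs)) || length(p$channel_names) != length(chn)) {
      stop("datasets differ in sampling rate or channel layout")
    }
  }
  epoched_dataset(
    trials = do.call(c, lapply(parts, `[[`, "trials")),
    labels = do.call(c, lapply(parts, `[[`, "labels")),
    fs = fs, channel_names = chn
  )
}

# Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
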