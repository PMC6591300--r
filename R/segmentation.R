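#' Sliding-window parameters
#'
#' Validated container for the trial segmentation: window length `l`,
#' overlap `t` (both in samples) for trials of `S` samples. Requires
#' `0 < t < l <= S`.
#'
#' @param l window length in samples.
#' @param t overlap between consecutive windows, in samples.
#' @param S trial length in samples.
#' @return A `window_params` list.
#' @export
window_params <- function(l, t, S) {
  l <- as.integer(l); t <- as.integer(t); S <- as.integer(S)
  if (!(t > 0L && l > t && S >= l)) {
    stop("window parameters must satisfy 0 < t < l <= S (got l=", l,
         ", t=", t, ", S=", S, ")")
  }
  structure(list(l = l, t = t, S = S), class = "window_params")
}

#' Default sliding-window parameters
#'
#' Window length 25% of the trial length and overlap 5% of the trial length
#' (round half up), the setting used for the sequence input of the LSTM.
#'
#' @param S trial length in samples (>= 8).
#' @return A [window_params()] with `l = round(0.25 * S)`,
#'   `t = round(0.05 * S)`.
#' @export
default_window_params <- function(S) {
  if (S < 8L) stop("trial too short for default windowing (S >= 8 required)")
  window_params(round_half_up(0.25 * S), round_half_up(0.05 * S), S)
}

#' Window start indices for a trial
#'
#' Starts advance by the step `l - t` while a full window fits; if the last
#' such window ends before `S`, one final window is re-anchored to end
#' exactly at `S`, so every sample of the trial is covered by at least one
#' window and no window extends past the trial (no padding).
#'
#' @param p a [window_params()].
#' @return Integer vector of 0-based window start indices.
#' @export
window_starts <- function(p) {
  stopifnot(inherits(p, "window_params"))
  step <- p$l - p$t
  starts <- seq.int(0L, p$S - p$l, by = step)
  last_end <- starts[length(starts)] + p$l
  if (last_end < p$S) starts <- c(starts, p$S - p$l)
  as.integer(starts)
}

#' Segment a trial into overlapping windows
#'
#' @param E channels x samples trial matrix.
#' @param p a [window_params()]; `p$S` must equal `ncol(E)`.
#' @return List of channels x `l` matrices, one per window, in time order.
#' @export
segment_trial <- function(E, p) {
  stopifnot(is.matrix(E), inherits(p, "window_params"))
  if (ncol(E) != p$S) {
    stop("trial has ", ncol(E), " samples but window_params expect ", p$S)
  }
  lapply(window_starts(p), function(s0) {
    E[, (s0 + 1L):(s0 + p$l), drop = FALSE]
  })
}

#' Per-trial sequence feature matrix
#'
#' Builds the N x d matrix whose j-th row holds the CSP log-variance
#' features of the j-th window of the trial — the sequence input consumed by
#' the LSTM regressor.
#'
#' @param E channels x samples trial matrix.
#' @param p a [window_params()].
#' @param bank the segment-level `spatial_filter_bank`.
#' @return An N x d numeric matrix (N windows, d = number of filters).
#' @export
build_sequence_features <- function(E, p, bank) {
  wins <- segment_trial(E, p)
  t(vapply(wins,
           function(w) csp_features(apply_spatial_filter(bank, w)),
           numeric(ncol(if (inherits(bank, "spatial_filter_bank")) bank$W
                        else bank))))
}

#' Pool the windows of every trial into one segment-level dataset
#'
#' Each window inherits its trial's label; the pooled segments are what the
#' segment-level CSP bank is learned from (training trials only).
#'
#' @param data an [epoched_dataset()].
#' @param p a [window_params()].
#' @return An [epoched_dataset()] of `N * n_trials` windows.
#' @export
pool_segments <- function(data, p) {
  stopifnot(inherits(data, "epoched_dataset"))
  segs <- list()
  labs <- character(0)
  for (i in seq_along(data$trials)) {
    w <- segment_trial(data$trials[[i]], p)
    segs <- c(segs, w)
    labs <- c(labs, rep(data$labels[i], length(w)))
  }
  epoched_dataset(segs, labs, data$fs, data$channel_names)
}
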