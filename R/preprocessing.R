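#' Band-pass filter specification
#'
#' Butterworth passband specification used throughout the pipeline. Defaults
#' to the 7-30 Hz band covering the mu and beta rhythms that carry
#' event-related desynchronization during motor imagery.
#'
#' @param low,high passband cutoff frequencies in Hz (-3 dB points of the
#'   analog Butterworth prototype).
#' @param order filter order of the underlying low/high-pass prototype
#'   (default 4; the band-pass filter has twice this order).
#' @param zero_phase apply the filter forward and backward (default TRUE),
#'   doubling the effective attenuation and cancelling phase distortion.
#' @return A `bandpass_spec` list.
#' @export
bandpass_spec <- function(low = 7, high = 30, order = 4, zero_phase = TRUE) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (order < 1) stop("order must be >= 1")
  structure(list(low = low, high = high, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "bandpass_spec")
}

#' Cut a continuous recording into trials
#'
#' Extracts one trial per cue marker, starting `offset_s` seconds after the
#' cue and lasting `length_s` seconds. Markers are 0-based sample indices;
#' each epoch covers the half-open sample interval
#' `[marker + round(offset_s * fs), marker + round(offset_s * fs) + round(length_s * fs))`.
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate, Hz.
#' @param markers integer vector of 0-based cue sample indices.
#' @param labels class id per marker.
#' @param offset_s cue-to-epoch offset in seconds (default 0.5).
#' @param length_s epoch length in seconds (default 2).
#' @param channel_names optional channel names.
#' @return An [epoched_dataset()].
#' @export
epoch_trials <- function(signal, fs, markers, labels,
                         offset_s = 0.5, length_s = 2.0,
                         channel_names = NULL) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (length(labels) != length(markers)) {
    stop("`labels` and `markers` must have equal length")
  }
  offset <- round_half_up(offset_s * fs)
  n_len <- round_half_up(length_s * fs)
  n_total <- ncol(signal)
  trials <- lapply(seq_along(markers), function(i) {
    start <- markers[i] + offset            # 0-based
    if (start < 0 || start + n_len > n_total) {
      stop("epoch for marker at sample ", markers[i],
           " exceeds recording bounds [0, ", n_total, ")")
    }
    signal[, (start + 1L):(start + n_len), drop = FALSE]
  })
  epoched_dataset(trials, labels, fs, channel_names)
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' that the output's per-sample channel mean is exactly zero.
#'
#' @param x a channels x samples matrix, or an [epoched_dataset()] (each
#'   trial is re-referenced).
#' @return Same type as the input.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "epoched_dataset")) {
    x$trials <- lapply(x$trials, common_average_reference)
    return(x)
  }
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("common average reference needs >= 2 channels")
  sweep(x, 2L, colMeans(x), `-`)
}

# Zero-phase Butterworth filtering of one channel with odd-reflection edge
# padding (keeps the 2 s epochs free of start-up transients). The channel
# mean is removed first: DC lies outside any passband and subtracting it
# avoids the long step transient it would otherwise inject.
filt_channel <- function(x, flt, zero_phase) {
  x <- x - mean(x)
  n <- length(x)
  pad <- min(n - 1L, 3L * (2L * length(flt$b)))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  if (zero_phase) {
    y <- as.numeric(signal::filtfilt(flt, xp))
  } else {
    y <- as.numeric(signal::filter(flt, xp))
  }
  y[(pad + 1L):(pad + n)]
}

#' Butterworth band-pass filter
#'
#' Filters each channel independently with a digital Butterworth band-pass
#' filter; with `zero_phase = TRUE` (default) the filter runs forward and
#' backward so no phase lag is introduced.
#'
#' @param x a channels x samples matrix, or an [epoched_dataset()].
#' @param fs sampling rate, Hz; taken from the dataset when `x` is an
#'   [epoched_dataset()].
#' @param spec a [bandpass_spec()].
#' @return Same type and shape as the input.
#' @export
bandpass_filter <- function(x, fs = NULL, spec = bandpass_spec()) {
  stopifnot(inherits(spec, "bandpass_spec"))
  if (inherits(x, "epoched_dataset")) {
    x$trials <- lapply(x$trials, bandpass_filter, fs = x$fs, spec = spec)
    return(x)
  }
  stopifnot(is.matrix(x), is.numeric(fs))
  if (spec$high >= fs / 2) {
    stop("high cutoff (", spec$high, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  }
  flt <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                        type = "pass")
  out <- t(apply(x, 1L, filt_channel, flt = flt,
                 zero_phase = spec$zero_phase))
  dimnames(out) <- dimnames(x)
  out
}

#' Standard preprocessing chain
#'
#' Applies, in order: common average reference, then band-pass filtering —
#' the per-trial processing applied to every epoch before spatial filtering.
#'
#' @param data an [epoched_dataset()].
#' @param spec a [bandpass_spec()].
#' @return The preprocessed [epoched_dataset()].
#' @export
preprocess <- function(data, spec = bandpass_spec()) {
  stopifnot(inherits(data, "epoched_dataset"))
  bandpass_filter(common_average_reference(data), spec = spec)
}
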