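#' Configuration for the synthetic MI-EEG generator
#'
#' The generator emulates two-class motor-imagery (MI) trials: two latent
#' cortical sources carry narrow-band (mu-rhythm-like) oscillations whose
#' band power differs between classes in a mirrored, lateralized way, mixed
#' into all channels through a random orthogonal mixing matrix on top of
#' 1/f background noise. A separate non-task class carries sporadic
#' high-amplitude low-frequency deflections (an eye-blink surrogate).
#'
#' @param n_channels number of EEG channels (>= 2).
#' @param fs sampling rate, Hz.
#' @param trial_seconds trial length in seconds; `fs * trial_seconds` must be
#'   a whole number of samples.
#' @param n_trials_per_class trials generated per class.
#' @param classes class ids; the first two are the MI classes, `"nontask"`
#'   names the non-task class used by [generate_nontask_trials()].
#' @param source_band frequency interval (Hz) of the discriminative sources.
#' @param power_ratio band-power ratio (>= 1) between the favoured and the
#'   suppressed class at each lateralized source.
#' @param noise_exponent slope of the 1/f^a background noise spectrum.
#' @param snr ratio of the suppressed-class source band power to the
#'   per-channel background noise power.
#' @param mixing_seed,noise_seed integer seeds for the mixing matrix and for
#'   everything else stochastic (phases, carrier frequencies, noise).
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_channels = 8, fs = 100, trial_seconds = 2,
                             n_trials_per_class = 50,
                             classes = c("left", "right"),
                             source_band = c(8, 12), power_ratio = 4,
                             noise_exponent = 1, snr = 5,
                             mixing_seed = 101, noise_seed = 202) {
  n_samples <- fs * trial_seconds
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("fs * trial_seconds must be an integer sample count")
  }
  if (n_channels < 2 || n_trials_per_class < 1) {
    stop("all counts must be >= 1 and n_channels >= 2")
  }
  if (power_ratio < 1) stop("power_ratio must be >= 1")
  if (length(source_band) != 2L || source_band[1L] >= source_band[2L] ||
      source_band[2L] >= fs / 2) {
    stop("source_band must be an increasing interval below fs/2")
  }
  if (snr <= 0) stop("snr must be positive")
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         trial_seconds = trial_seconds,
         n_samples = as.integer(round(n_samples)),
         n_trials_per_class = as.integer(n_trials_per_class),
         classes = as.character(classes), source_band = source_band,
         power_ratio = power_ratio, noise_exponent = noise_exponent,
         snr = snr, mixing_seed = as.integer(mixing_seed),
         noise_seed = as.integer(noise_seed)),
    class = "synthetic_config"
  )
}

# Orthogonal mixing matrix (QR of a Gaussian matrix), deterministic per seed.
mixing_matrix <- function(config) {
  with_seed(config$mixing_seed, {
    g <- matrix(stats::rnorm(config$n_channels^2), config$n_channels)
    q <- qr.Q(qr(g))
    # fix column signs for reproducibility across BLAS variants
    s <- sign(q[cbind(max.col(t(abs(q))), seq_len(ncol(q)))])
    s[s == 0] <- 1
    sweep(q, 2L, s, `*`)
  })
}

# 1/f^a Gaussian noise, one channel per row, unit variance per channel.
colored_noise <- function(n_channels, n_samples, exponent) {
  out <- matrix(0, n_channels, n_samples)
  freqs <- seq(0, n_samples - 1) / n_samples
  freqs <- pmin(freqs, 1 - freqs)           # two-sided frequency magnitude
  scale <- ifelse(freqs > 0, freqs^(-exponent / 2), 0)
  for (ch in seq_len(n_channels)) {
    spec <- stats::fft(stats::rnorm(n_samples)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

# Amplitude-modulated narrow-band sinusoid of unit RMS (before scaling).
narrowband_source <- function(n_samples, fs, band) {
  f <- stats::runif(1L, band[1L], band[2L])
  phase <- stats::runif(1L, 0, 2 * pi)
  mod_phase <- stats::runif(1L, 0, 2 * pi)
  tt <- seq_len(n_samples) / fs
  env <- 1 + 0.5 * sin(2 * pi * 1 * tt + mod_phase)
  x <- env * sin(2 * pi * f * tt + phase)
  x / sqrt(mean(x^2))
}

# Per-class source amplitudes: source 1 favours class 1, source 2 favours
# class 2 (mirrored lateralization).  The suppressed-class source variance
# equals `snr` (noise has unit variance per channel).
source_amplitudes <- function(config) {
  a_low <- sqrt(config$snr)
  a_high <- a_low * sqrt(config$power_ratio)
  list(high = a_high, low = a_low)
}

#' Generate a balanced synthetic two-class MI dataset
#'
#' Two designated latent sources carry class-dependent narrow-band power with
#' the configured ratio (`power_ratio`), mixed into all channels via a random
#' orthogonal matrix, plus 1/f background noise. Fully reproducible from the
#' seeds in the config.
#'
#' @param config a [synthetic_config()].
#' @return An [epoched_dataset()] with `2 * n_trials_per_class` trials,
#'   labels alternating over the first two configured classes, and attributes
#'   `mixing` (the mixing matrix) and `config`.
#' @export
generate_mi_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  A <- mixing_matrix(config)
  amp <- source_amplitudes(config)
  cls <- config$classes[1:2]
  n <- config$n_trials_per_class
  labels <- rep(cls, each = n)
  trials <- with_seed(config$noise_seed, {
    lapply(seq_along(labels), function(i) {
      s1 <- narrowband_source(config$n_samples, config$fs, config$source_band)
      s2 <- narrowband_source(config$n_samples, config$fs, config$source_band)
      if (labels[i] == cls[1L]) {
        src <- rbind(amp$high * s1, amp$low * s2)
      } else {
        src <- rbind(amp$low * s1, amp$high * s2)
      }
      noise <- colored_noise(config$n_channels, config$n_samples,
                             config$noise_exponent)
      A[, 1:2] %*% src + noise
    })
  })
  out <- epoched_dataset(trials, labels, config$fs)
  attr(out, "mixing") <- A
  attr(out, "config") <- config
  out
}

#' Generate synthetic non-task trials
#'
#' Trials of background 1/f noise with sporadic high-amplitude low-frequency
#' bumps (an eye-blink surrogate) whose peak amplitude is at least three
#' times the MI source amplitude, so their statistics differ from MI trials
#' while remaining non-trivial after band-pass filtering.
#'
#' @param config a [synthetic_config()]; `n_trials_per_class` non-task trials
#'   are produced.
#' @param n_trials optional override of the number of trials.
#' @return An [epoched_dataset()] with all trials labeled `"nontask"`.
#' @export
generate_nontask_trials <- function(config, n_trials = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n_trials)) n_trials <- config$n_trials_per_class
  A <- mixing_matrix(config)
  amp <- source_amplitudes(config)
  bump_amp <- 4 * amp$high                   # >= 3x source amplitude
  trials <- with_seed(config$noise_seed + 1L, {
    lapply(seq_len(n_trials), function(i) {
      noise <- colored_noise(config$n_channels, config$n_samples,
                             config$noise_exponent)
      blink <- numeric(config$n_samples)
      n_bumps <- sample(1:3, 1L)
      width <- 0.15 * config$fs              # ~0.3 s bumps, sub-5 Hz content
      for (b in seq_len(n_bumps)) {
        center <- stats::runif(1L, 0.1, 0.9) * config$n_samples
        tt <- seq_len(config$n_samples)
        blink <- blink + bump_amp * exp(-((tt - center)^2) / (2 * width^2))
      }
      # blink projects mostly onto the first mixing column (frontal-like)
      topo <- A[, 1L] + 0.2 * A[, 2L]
      noise + topo %*% t(blink)
    })
  })
  out <- epoched_dataset(trials, rep("nontask", n_trials), config$fs)
  attr(out, "mixing") <- A
  attr(out, "config") <- config
  out
}

#' Generate a continuous recording with cue markers
#'
#' Embeds the trials of [generate_mi_dataset()] verbatim into a continuous
#' background-noise record, each trial starting 0.5 s after its cue marker,
#' so that epoching at (cue + 0.5 s, 2 s) recovers the embedded trials
#' exactly.
#'
#' @param config a [synthetic_config()].
#' @param offset_s cue-to-trial offset in seconds (default 0.5).
#' @param gap_s silence between the end of one trial and the next cue;
#'   must leave inter-cue gaps of at least `offset_s + trial_seconds` or an
#'   error is raised.
#' @return A list with `signal` (channels x samples matrix), `fs`,
#'   `markers` (0-based cue sample indices), `labels`, and `dataset` (the
#'   embedded [epoched_dataset()]).
#' @export
generate_raw_with_markers <- function(config, offset_s = 0.5, gap_s = 1.0) {
  stopifnot(inherits(config, "synthetic_config"))
  ds <- generate_mi_dataset(config)
  n_trials <- length(ds)
  offset <- round_half_up(offset_s * config$fs)
  span <- offset + config$n_samples
  step <- span + round_half_up(gap_s * config$fs)
  if (step < span) {
    stop("marker collision: inter-cue gap (", step,
         " samples) is shorter than the epoch span (", span, " samples)")
  }
  lead <- round_half_up(0.5 * config$fs)
  total <- lead + n_trials * step
  markers <- lead + (seq_len(n_trials) - 1L) * step   # 0-based
  signal <- with_seed(config$noise_seed + 2L,
                      colored_noise(config$n_channels, total,
                                    config$noise_exponent))
  for (i in seq_len(n_trials)) {
    start <- markers[i] + offset              # 0-based start of the epoch
    signal[, (start + 1L):(start + config$n_samples)] <- ds$trials[[i]]
  }
  list(signal = signal, fs = config$fs, markers = as.integer(markers),
       labels = ds$labels, dataset = ds)
}
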