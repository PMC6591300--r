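# Small seeded fixtures shared across tests.

small_config <- function(n_trials_per_class = 20, snr = 5, power_ratio = 4,
                         noise_seed = 11, mixing_seed = 7, ...) {
  synthetic_config(n_channels = 8, fs = 100, trial_seconds = 2,
                   n_trials_per_class = n_trials_per_class,
                   power_ratio = power_ratio, snr = snr,
                   mixing_seed = mixing_seed, noise_seed = noise_seed, ...)
}

small_preprocessed <- function(...) {
  suppressWarnings(preprocess(generate_mi_dataset(small_config(...))))
}

# mean band power of one channel over trials, by periodogram (independent
# spectral oracle: plain FFT periodogram, no package filtering involved)
periodogram_band_power <- function(trials, channel, fs, band) {
  mean(vapply(trials, function(tr) {
    x <- tr[channel, ]
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n
    freqs <- (seq_len(n) - 1) * fs / n
    sel <- freqs >= band[1] & freqs <= band[2]
    sum(p[sel]) / n
  }, numeric(1)))
}
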