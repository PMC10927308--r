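# shared small fixtures

# a deterministic multichannel recording of pure tones plus faint noise
tone_recording <- function(freqs_hz, fs = 256, duration = 10,
                           noise_sd = 0) {
  t <- seq(1 / fs, duration, by = 1 / fs)
  data <- t(vapply(freqs_hz, function(f0) sin(2 * pi * f0 * t),
                   numeric(length(t))))
  if (noise_sd > 0) {
    data <- data + matrix(stats::rnorm(length(data), 0, noise_sd),
                          nrow(data))
  }
  eeg_recording(data, fs)
}

# desk-size synthetic study configuration for pipeline tests: 8 channels
# with a small explicit coupling layout
tiny_config <- function(n_subjects = 4, seed = 7, duration = 36,
                        fs = 128) {
  labels <- sprintf("ch%02d", 1:8)
  coupling <- tibble::tibble(
    band = c("theta", "theta", "delta"),
    chan_i = c("ch01", "ch03", "ch05"),
    chan_j = c("ch02", "ch04", "ch06"),
    lag = pi / 2,
    strength = c(0.5, 0.5, 0.5)
  )
  synth_config(
    n_subjects = n_subjects, fs = fs, duration = duration, n_channels = 8,
    coupling_spec = coupling, seed = seed
  )
}

band_wpli_of_pair <- function(pair, fs, band, epoch_s = 12, n_tapers = 7) {
  rec <- eeg_recording(pair, fs)
  ep <- epoch_recording(rec, epoch_s)
  W <- wpli_matrix(ep, band, n_tapers = n_tapers)
  W[1, 2]
}
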