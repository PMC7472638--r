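# Shared fixtures: small configurations and hand-built objects used across
# the module tests. Everything is generated in code; no data files.

# Short, low-rate generator configuration for tests that only need the
# band-power structure, not the full 63 s protocol trial.
fast_cfg <- function(...) {
  args <- list(content_duration = 8, baseline_duration = 1,
               fs_raw = 128, n_channels_total = 32, seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# A processed trial with arbitrary content, for segmentation / model tests.
stub_processed_trial <- function(seed = 1, rating_v = 7, rating_a = 5,
                                 participant = 1, trial = 1) {
  d <- eegcontrast:::with_seed(seed, matrix(stats::rnorm(32 * 7680), 32))
  structure(list(
    data = d, fs = 128, channel_labels = deap_channel_labels(),
    participant = participant, trial = trial, content = 1,
    condition = NULL, rating_valence = rating_v, rating_arousal = rating_a,
    latent_valence = 0, latent_arousal = 0
  ), class = "processed_trial")
}

# Mid-range random image (no component near 0 or 1), so contrast
# adjustments at moderate alpha never clip and hue is never degenerate.
midrange_image <- function(seed = 1, h = 12, w = 12) {
  eegcontrast:::with_seed(seed, {
    hsv <- list(h = matrix(stats::runif(h * w), h, w),
                s = matrix(stats::runif(h * w, 0.3, 0.7), h, w),
                v = matrix(stats::runif(h * w, 0.3, 0.7), h, w))
    hsv_to_rgb(hsv)
  })
}

# Build an RGB image from an explicit V plane (S = 0 everywhere), so pixel
# intensity (the V plane) is exactly the supplied values.
gray_image <- function(v) {
  m <- as.matrix(v)
  out <- array(0, c(dim(m), 3))
  out[, , 1] <- m; out[, , 2] <- m; out[, , 3] <- m
  out
}

# A pure-sinusoid multichannel trial for filter oracles.
sinusoid_trial <- function(freq, fs, duration, n_ch = 4, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  structure(list(
    data = matrix(rep(x, each = n_ch), n_ch),
    fs = fs, channel_labels = deap_channel_labels()[seq_len(n_ch)],
    condition = NULL, rating_valence = 5, rating_arousal = 5,
    latent_valence = 0, latent_arousal = 0,
    baseline_samples = 0L
  ), class = "eeg_trial")
}

rms <- function(x) sqrt(mean(x^2))
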