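# DEAP-style preprocessing: downsample to 128 Hz, band-pass 4-45 Hz,
# drop the 8 peripheral channels, trim the baseline, crop to 60 s.

#' Downsample a trial
#'
#' Fourier-domain resampling (the ideal anti-alias filter followed by
#' decimation, computed as spectral truncation): the spectrum is cut at the
#' new Nyquist frequency and inverse-transformed at the new rate. Exact for
#' band-limited content and zero-phase by construction; handles any rate
#' ratio for which the output length is an integer.
#'
#' @param trial an `eeg_trial`.
#' @param target_fs target sampling rate in Hz (default 128).
#' @return the trial resampled to `target_fs`.
#' @export
downsample <- function(trial, target_fs = 128) {
  if (target_fs > trial$fs) stopf("target rate above source rate")
  if (target_fs == trial$fs) return(trial)
  n <- ncol(trial$data)
  n_out <- n * target_fs / trial$fs
  if (abs(n_out - round(n_out)) > 1e-9)
    stopf("rate ratio %g/%g does not give a whole number of samples",
          target_fs, trial$fs)
  n_out <- as.integer(round(n_out))
  spec <- stats::mvfft(t(trial$data))             # n x channels
  out_spec <- matrix(0 + 0i, n_out, nrow(trial$data))
  nh <- (n_out - 1L) %/% 2L                       # kept positive bins
  out_spec[1L, ] <- spec[1L, ]
  out_spec[2:(nh + 1L), ] <- spec[2:(nh + 1L), ]
  out_spec[seq(n_out, n_out - nh + 1L), ] <- spec[seq(n, n - nh + 1L), ]
  out <- Re(stats::mvfft(out_spec, inverse = TRUE)) / n
  trial$data <- t(out)
  trial$baseline_samples <-
    as.integer(round(trial$baseline_samples * target_fs / trial$fs))
  trial$fs <- target_fs
  trial
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth band-pass applied with zero phase: the squared
#' magnitude response |H(f)|^2 of the forward-backward cascade is applied
#' in the frequency domain, vectorized over channels. The normative
#' contract is the response, not the realization: gain within 1 dB at
#' 10 Hz, attenuation of at least 20 dB at 1 Hz and at 60 Hz where
#' representable.
#'
#' @param trial an `eeg_trial`.
#' @param low,high band edges in Hz (default 4 and 45).
#' @return the filtered trial.
#' @export
bandpass <- function(trial, low = 4, high = 45) {
  if (!(0 < low && low < high && high < trial$fs / 2))
    stopf("band [%g, %g] infeasible at fs = %g", low, high, trial$fs)
  bf <- signal::butter(4, c(low, high) / (trial$fs / 2), type = "pass")
  n <- ncol(trial$data)
  # |H|^2 of the Butterworth cascade at every FFT bin (two-sided)
  f <- (0:(n - 1)) / n                       # cycles/sample
  f <- ifelse(f > 0.5, f - 1, f)
  w <- exp(-2i * pi * f)
  pw <- outer(w, 0:(length(bf$b) - 1), `^`)
  h <- as.vector(pw %*% bf$b) / as.vector(pw %*% bf$a)
  gain2 <- Mod(h)^2
  spec <- stats::mvfft(t(trial$data)) * gain2
  trial$data <- t(Re(stats::mvfft(spec, inverse = TRUE)) / n)
  trial
}

#' Retain the 32 EEG channels in DEAP order
#'
#' Drops the eight peripheral rows and reorders the remaining channels to
#' the canonical DEAP montage regardless of input row order.
#'
#' @param trial an `eeg_trial` with labelled channels.
#' @return the trial with exactly the 32 EEG rows.
#' @export
select_eeg_channels <- function(trial) {
  want <- deap_channel_labels()
  idx <- match(want, trial$channel_labels)
  if (anyNA(idx))
    stopf("missing expected EEG channels: %s",
          paste(want[is.na(idx)], collapse = ", "))
  trial$data <- trial$data[idx, , drop = FALSE]
  trial$channel_labels <- want
  trial
}

#' Trim the baseline and crop to the analysis window
#'
#' Drops the first `baseline_s` seconds and keeps exactly the next
#' `content_s` seconds (7680 samples at 128 Hz); longer content (clips
#' played for 60-90 s) is truncated.
#'
#' @param trial an `eeg_trial` (typically already at 128 Hz, 32 channels).
#' @param baseline_s,content_s baseline and analysis window in seconds.
#' @return a `processed_trial`: the cropped matrix plus provenance.
#' @export
trim_and_crop <- function(trial, baseline_s = 3, content_s = 60) {
  n_base <- as.integer(round(baseline_s * trial$fs))
  n_keep <- as.integer(round(content_s * trial$fs))
  if (ncol(trial$data) < n_base + n_keep)
    stopf("trial too short: need %d samples, have %d",
          n_base + n_keep, ncol(trial$data))
  out <- trial$data[, (n_base + 1):(n_base + n_keep), drop = FALSE]
  structure(list(
    data = out, fs = trial$fs, channel_labels = trial$channel_labels,
    participant = trial$participant, trial = trial$trial,
    content = trial$content, condition = trial$condition,
    rating_valence = trial$rating_valence,
    rating_arousal = trial$rating_arousal,
    latent_valence = trial$latent_valence,
    latent_arousal = trial$latent_arousal
  ), class = "processed_trial")
}

#' Full preprocessing pipeline for one trial
#'
#' downsample -> band-pass -> EEG channel selection -> baseline trim + crop.
#' For a 63 s raw trial this yields the canonical 32 x 7680 matrix at
#' 128 Hz. Optionally subtracts the per-channel baseline-window mean before
#' trimming (the protocol emits a baseline but the analyses discard it).
#'
#' @param trial an `eeg_trial`.
#' @param target_fs target rate (Hz).
#' @param low,high band-pass edges (Hz).
#' @param baseline_s,content_s trim/crop window (seconds).
#' @param baseline_subtract subtract the baseline-window mean per channel.
#' @return a `processed_trial` (32 x 7680 at the defaults).
#' @export
preprocess_trial <- function(trial, target_fs = 128, low = 4, high = 45,
                             baseline_s = 3, content_s = 60,
                             baseline_subtract = FALSE) {
  tr <- downsample(trial, target_fs)
  tr <- bandpass(tr, low, high)
  tr <- select_eeg_channels(tr)
  if (baseline_subtract) {
    n_base <- as.integer(round(baseline_s * tr$fs))
    if (n_base > 0) {
      mu <- rowMeans(tr$data[, seq_len(n_base), drop = FALSE])
      tr$data <- tr$data - mu
    }
  }
  trim_and_crop(tr, baseline_s, content_s)
}
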