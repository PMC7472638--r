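# Synthetic DEAP-shaped EEG with label-linked spectral structure.
#
# Latent valence is carried by the inter-hemispheric alpha-band (8-13 Hz)
# log-power asymmetry of the frontal pair F3/F4; latent arousal by the mean
# beta-band (13-30 Hz) log-power over the EEG channels. Both ride on a 1/f
# background, so nothing downstream can cheat by reading a clean sinusoid.

#' Configuration for the synthetic EEG generator
#'
#' The defaults encode the study conditions: a DEAP-shaped corpus
#' (32 participants x 40 rated trials, 60 s content + 3 s baseline,
#' 40 channels of which 32 are EEG), generation at DEAP's native 512 Hz so
#' preprocessing exercises the downsampling path, a valence effect injected
#' as alpha-asymmetry slope 3 per unit latent valence (sized so the
#' recognizer's window-limited decoding separates the contrast conditions
#' the way the full-trial feature does), and an active arousal slope with
#' latent arousal held at zero in every protocol condition.
#'
#' @param n_participants,trials_per_participant corpus dimensions.
#' @param fs_raw generation sampling rate in Hz (>= 256).
#' @param fs_target preprocessing target rate in Hz.
#' @param content_duration,baseline_duration seconds of content and of
#'   baseline prefix per trial.
#' @param n_channels_total,n_eeg_channels total and EEG-only channel counts.
#' @param valence_effect alpha-asymmetry slope per unit latent valence
#'   (dimensionless, on the log-power scale).
#' @param arousal_effect beta log-power slope per unit latent arousal.
#' @param noise_exponent 1/f^exponent slope of the background power spectrum.
#' @param pink_rms,alpha_rms,beta_rms amplitudes in microvolts RMS:
#'   background per channel, total alpha-band (8-13 Hz) amplitude of the
#'   frontal pair at zero asymmetry, total beta-band (13-30 Hz) amplitude
#'   per EEG channel at zero arousal.
#' @param asym_noise_sd,beta_noise_sd trial-level noise SD on the injected
#'   log-power quantities.
#' @param asym_participant_sd,beta_participant_sd SD of per-participant
#'   offsets on the same quantities. Alpha asymmetry is a difference of
#'   homologous channels, which cancels most individual broadband
#'   differences, so its participant spread is small; absolute beta power
#'   varies substantially between individuals.
#' @param rating_noise_sd additive Gaussian rating noise on the 1-9 scale.
#' @param contrast_shift latent-valence shift for contrast-up (+) and
#'   contrast-down (-) conditions; encodes the study's finding that contrast
#'   moves valence without overtaking the adjacent emotion class.
#' @param emotion_latents named latent valence per emotion category.
#' @param seed master seed; all per-trial seeds derive from it.
#' @return validated `synth_config` list.
#' @export
synth_config <- function(n_participants = 32, trials_per_participant = 40,
                         fs_raw = 512, fs_target = 128,
                         content_duration = 60, baseline_duration = 3,
                         n_channels_total = 40, n_eeg_channels = 32,
                         valence_effect = 3, arousal_effect = 1,
                         noise_exponent = 1,
                         pink_rms = 5, alpha_rms = 8, beta_rms = 5,
                         asym_noise_sd = 0.05, beta_noise_sd = 0.05,
                         asym_participant_sd = 0.03,
                         beta_participant_sd = 0.3,
                         rating_noise_sd = 0.5,
                         contrast_shift = 0.15,
                         emotion_latents = c(negative = -0.7, neutral = 0,
                                             positive = 0.7),
                         seed = 1L) {
  cfg <- list(
    n_participants = n_participants,
    trials_per_participant = trials_per_participant,
    fs_raw = fs_raw, fs_target = fs_target,
    content_duration = content_duration,
    baseline_duration = baseline_duration,
    n_channels_total = n_channels_total, n_eeg_channels = n_eeg_channels,
    valence_effect = valence_effect, arousal_effect = arousal_effect,
    noise_exponent = noise_exponent,
    pink_rms = pink_rms, alpha_rms = alpha_rms, beta_rms = beta_rms,
    asym_noise_sd = asym_noise_sd, beta_noise_sd = beta_noise_sd,
    asym_participant_sd = asym_participant_sd,
    beta_participant_sd = beta_participant_sd,
    rating_noise_sd = rating_noise_sd,
    contrast_shift = contrast_shift,
    emotion_latents = emotion_latents,
    seed = as.integer(seed)
  )
  for (f in c("n_participants", "trials_per_participant", "n_channels_total",
              "n_eeg_channels"))
    if (!is_count(cfg[[f]])) stopf("%s must be a positive integer", f)
  if (cfg$fs_raw < 2 * 45) stopf("fs_raw too low: the 4-45 Hz band needs fs_raw >= 90")
  if (cfg$fs_raw < cfg$fs_target) stopf("fs_raw must be >= fs_target")
  if (cfg$content_duration <= 0 || cfg$baseline_duration < 0)
    stopf("durations must be positive")
  if (cfg$valence_effect < 0 || cfg$arousal_effect < 0)
    stopf("effect sizes must be >= 0")
  if (!all(c("negative", "neutral", "positive") %in% names(cfg$emotion_latents)))
    stopf("emotion_latents must name negative, neutral, positive")
  class(cfg) <- "synth_config"
  cfg
}

# ---- spectral synthesis -----------------------------------------------

# Random Hermitian spectra for m channels: a list with the positive-
# frequency coefficient matrix (nh x m), frequencies, and the assembly
# routine. Band powers can be rescaled exactly on the half-spectrum before
# assembly, so injected log-power quantities are exact by construction.
half_spectrum <- function(n, m, fs, shape) {
  n <- as.integer(n)
  nh <- (n - 1L) %/% 2L                 # strictly positive, non-Nyquist bins
  f <- (1:nh) * fs / n
  amp <- shape(f)
  coef <- (matrix(stats::rnorm(nh * m), nh, m) +
             1i * matrix(stats::rnorm(nh * m), nh, m)) * amp
  list(coef = coef, f = f, n = n, m = m)
}

# Total signal variance contributed by bins `sel` of each channel, under
# the x = Re(ifft) convention below (Nyquist bin omitted; its power is
# negligible for 1/f-shaped spectra).
band_power_of <- function(hs, sel) 2 * colSums(Mod(hs$coef[sel, , drop = FALSE])^2) / hs$n^2

# Rescale the selected bins of channels `cols` so their band power is
# exactly `target` (vector over cols).
rescale_band <- function(hs, sel, cols, target) {
  cur <- band_power_of(hs, sel)[cols]
  cur[cur == 0] <- 1
  hs$coef[sel, cols] <- sweep(hs$coef[sel, cols, drop = FALSE], 2,
                              sqrt(target / cur), `*`)
  hs
}

# Assemble real time-domain signals (n x m) from the half spectrum.
assemble_signals <- function(hs) {
  n <- hs$n
  nh <- nrow(hs$coef)
  spec <- matrix(0 + 0i, n, hs$m)
  spec[2:(nh + 1L), ] <- hs$coef
  spec[seq(n, n - nh + 1L), ] <- Conj(hs$coef)
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

pink_noise <- function(n, fs, m, exponent, rms) {
  hs <- half_spectrum(n, m, fs, function(f) f^(-exponent / 2))
  x <- assemble_signals(hs)
  sd0 <- sqrt(colMeans(x^2))
  sd0[sd0 == 0] <- 1
  sweep(x, 2, rms / sd0, `*`)
}

# ---- band-power measurement -------------------------------------------

#' Periodogram band log-power
#'
#' Natural log of the signal variance contributed by the frequency band
#' `[low, high]`, from the raw periodogram.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @return scalar log-power.
#' @export
band_log_power <- function(x, fs, low, high) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  psd <- Mod(stats::fft(x))^2 / n^2
  keep <- f >= low & f <= high & f <= fs / 2
  log(2 * sum(psd[keep]))
}

#' Frontal alpha-band asymmetry of a trial
#'
#' Left-minus-right frontal (F3 - F4) alpha-band (8-13 Hz) log-power
#' difference, the generator's carrier for latent valence.
#'
#' @param trial an `eeg_trial` or `processed_trial`.
#' @return scalar asymmetry.
#' @export
alpha_asymmetry <- function(trial) {
  pair <- asymmetry_pair()
  i_l <- match(pair["left"], trial$channel_labels)
  i_r <- match(pair["right"], trial$channel_labels)
  if (anyNA(c(i_l, i_r))) stopf("frontal pair %s/%s not found", pair[1], pair[2])
  band_log_power(trial$data[i_l, ], trial$fs, 8, 13) -
    band_log_power(trial$data[i_r, ], trial$fs, 8, 13)
}

#' Mean beta-band log-power of a trial
#'
#' Mean over EEG channels of the 13-30 Hz log-power, the generator's carrier
#' for latent arousal.
#'
#' @param trial an `eeg_trial` or `processed_trial`.
#' @return scalar log-power.
#' @export
beta_log_power <- function(trial) {
  eeg <- intersect(deap_channel_labels(), trial$channel_labels)
  idx <- match(eeg, trial$channel_labels)
  mean(vapply(idx, function(i)
    band_log_power(trial$data[i, ], trial$fs, 13, 30), 0))
}

# ---- trial / session / dataset generation -----------------------------

resolve_latents <- function(condition, latents, config, contrast_gain = 1) {
  if (!is.null(latents)) {
    lv <- latents[["valence"]]; la <- latents[["arousal"]]
  } else {
    if (is.null(condition)) stopf("give either a condition or explicit latents")
    emo <- match.arg(condition$emotion, c("negative", "neutral", "positive"))
    ctr <- match.arg(condition$contrast, c("down", "original", "up"))
    shift <- switch(ctr, up = 1, down = -1, original = 0) *
      config$contrast_shift * contrast_gain
    lv <- unname(config$emotion_latents[[emo]]) + shift
    la <- 0
  }
  if (abs(lv) > 1 || abs(la) > 1) stopf("latent values must lie in [-1, 1]")
  c(valence = unname(lv), arousal = unname(la))
}

#' Generate one synthetic EEG trial
#'
#' Produces a 40-channel trial (32 EEG + 8 peripheral, DEAP channel order) of
#' `baseline_duration + content_duration` seconds at `fs_raw`. The F3/F4
#' alpha-band log-power difference equals
#' `valence_effect * latent_valence` plus trial noise, and the mean beta-band
#' log-power equals a fixed baseline plus `arousal_effect * latent_arousal`
#' plus trial noise, over a 1/f background. Ratings are
#' `5 + 4 * latent + noise`, clipped to [1, 9]. Bit-identical output for
#' identical (config, seed).
#'
#' @param config a [synth_config()].
#' @param seed integer seed for this trial.
#' @param condition list(emotion =, contrast =) mapped to latents via the
#'   configured emotion latents and contrast shift; or NULL.
#' @param latents explicit c(valence =, arousal =) in [-1, 1]; overrides
#'   `condition`.
#' @param contrast_gain per-content multiplier on the contrast-driven latent
#'   shift (scene-diversity coupling).
#' @param asym_offset,beta_offset participant-level log-power offsets added
#'   to the injected asymmetry and beta quantities (see
#'   [participant_offsets()]).
#' @param duration content seconds; defaults to `config$content_duration`.
#' @return an `eeg_trial` object.
#' @export
generate_trial <- function(config, seed, condition = NULL, latents = NULL,
                           contrast_gain = 1, asym_offset = 0,
                           beta_offset = 0, duration = NULL) {
  lat <- resolve_latents(condition, latents, config, contrast_gain)
  dur <- if (is.null(duration)) config$content_duration else duration
  fs <- config$fs_raw
  n <- as.integer(round(fs * (dur + config$baseline_duration)))
  labels <- deap_channel_labels(peripheral = TRUE)
  labels <- labels[seq_len(config$n_channels_total)]
  n_eeg <- config$n_eeg_channels
  with_seed(seed, {
    x_asym <- config$valence_effect * lat[["valence"]] + asym_offset +
      stats::rnorm(1, 0, config$asym_noise_sd)
    x_beta <- config$arousal_effect * lat[["arousal"]] + beta_offset +
      stats::rnorm(1, 0, config$beta_noise_sd)
    data <- matrix(0, length(labels), n)
    # one shaped spectrum per EEG channel: 1/f background, then the alpha
    # and beta bands rescaled to their exact injected powers
    hs <- half_spectrum(n, n_eeg, fs, function(f) f^(-config$noise_exponent / 2))
    # normalize the background to pink_rms out of band
    sc <- sqrt(colMeans(assemble_signals(hs)^2))
    hs$coef <- sweep(hs$coef, 2, config$pink_rms / ifelse(sc == 0, 1, sc), `*`)
    beta_sel <- hs$f > 13 & hs$f <= 30
    hs <- rescale_band(hs, beta_sel, seq_len(n_eeg),
                       rep(config$beta_rms^2 * exp(x_beta), n_eeg))
    pair_idx <- match(asymmetry_pair(), labels)
    alpha_sel <- hs$f >= 8 & hs$f <= 13
    hs <- rescale_band(hs, alpha_sel, pair_idx,
                       config$alpha_rms^2 * exp(c(x_asym, -x_asym) / 2))
    data[1:n_eeg, ] <- t(assemble_signals(hs))
    # slow drift-like noise on the peripheral rows (present only so channel
    # exclusion has something to exclude)
    if (length(labels) > n_eeg)
      data[(n_eeg + 1):length(labels), ] <-
        t(pink_noise(n, fs, length(labels) - n_eeg, 2.5, 4 * config$pink_rms))
    rating <- function(l) min(9, max(1, 5 + 4 * l +
                                       stats::rnorm(1, 0, config$rating_noise_sd)))
    structure(list(
      data = data, fs = fs, channel_labels = labels,
      condition = condition,
      rating_valence = rating(lat[["valence"]]),
      rating_arousal = rating(lat[["arousal"]]),
      latent_valence = lat[["valence"]], latent_arousal = lat[["arousal"]],
      baseline_samples = as.integer(round(fs * config$baseline_duration))
    ), class = "eeg_trial")
  })
}

#' Participant-level band-power offsets
#'
#' Deterministic per-participant offsets on the asymmetry and beta
#' log-power scales, emulating stable individual differences in band power.
#'
#' @param participant_id integer id.
#' @param config a [synth_config()].
#' @return named vector c(asym, beta).
#' @export
participant_offsets <- function(participant_id, config) {
  with_seed(derive_seed(config$seed, 5L, participant_id), {
    c(asym = stats::rnorm(1, 0, config$asym_participant_sd),
      beta = stats::rnorm(1, 0, config$beta_participant_sd))
  })
}

#' Generate one 27-trial experiment session
#'
#' One participant's protocol session: three contrast blocks (all nine
#' original clips, then the nine with increased contrast, then the nine with
#' decreased contrast); within a block, the positive, neutral and negative
#' clip of each of the three contents in turn. Every trial carries a 3 s
#' baseline prefix.
#'
#' @param participant_id integer id (enters the per-trial seeds).
#' @param config a [synth_config()].
#' @param contrast_gains length-3 multiplier on the contrast latent shift,
#'   one per content (couples scene color diversity to the effect size).
#' @return list of 27 `eeg_trial` objects with `$participant`, `$content`
#'   and `$trial` fields set.
#' @export
generate_session <- function(participant_id, config, contrast_gains = c(1, 1, 1)) {
  if (length(contrast_gains) != 3) stopf("contrast_gains must have length 3")
  blocks <- c("original", "up", "down")
  emotions <- c("positive", "neutral", "negative")
  off <- participant_offsets(participant_id, config)
  trials <- vector("list", 27)
  i <- 0L
  for (b in blocks) for (content in 1:3) for (emo in emotions) {
    i <- i + 1L
    tr <- generate_trial(
      config, seed = derive_seed(config$seed, 1L, participant_id, i),
      condition = list(emotion = emo, contrast = b),
      contrast_gain = contrast_gains[content],
      asym_offset = off[["asym"]], beta_offset = off[["beta"]]
    )
    tr$participant <- participant_id
    tr$content <- content
    tr$trial <- i
    trials[[i]] <- tr
  }
  trials
}

#' Generate a DEAP-shaped rated dataset
#'
#' Emulates the DEAP corpus layout: `n_participants` x
#' `trials_per_participant` trials with latent valence/arousal drawn
#' uniformly from [-0.7, 0.7] and ratings tied to the latents. Because a
#' full-size corpus of raw waveforms is many gigabytes, the return value
#' carries the manifest plus a deterministic trial constructor; set
#' `signals = TRUE` to materialise every trial (small configs only).
#'
#' @param config a [synth_config()].
#' @param signals materialise all trials into memory.
#' @param latent_sampler optional `function(n)` returning an n x 2 matrix of
#'   (valence, arousal) latents. The default is a balanced factorial draw:
#'   magnitudes uniform on [0, 0.7] with all four sign combinations per
#'   quadruple, so valence and arousal latents span both rating sides and
#'   are exactly uncorrelated in sample — a corpus property that keeps the
#'   recognizer's two output heads from trading on spurious label
#'   correlation. Supply e.g. a two-level sampler for two-class designs.
#' @return list with `manifest` (data.frame: participant, trial,
#'   latent/rating columns, trial seed), `make_trial(i)` returning the i-th
#'   `eeg_trial`, and `trials` (list or NULL).
#' @export
generate_deap_like_dataset <- function(config, signals = FALSE,
                                       latent_sampler = NULL) {
  np <- config$n_participants; nt <- config$trials_per_participant
  n <- np * nt
  lat <- with_seed(derive_seed(config$seed, 2L), {
    if (is.null(latent_sampler)) balanced_latents(n)
    else latent_sampler(n)
  })
  manifest <- data.frame(
    participant = rep(seq_len(np), each = nt),
    trial = rep(seq_len(nt), np),
    latent_valence = lat[, 1], latent_arousal = lat[, 2]
  )
  manifest$seed <- mapply(function(p, t) derive_seed(config$seed, 3L, p, t),
                          manifest$participant, manifest$trial)
  rate <- with_seed(derive_seed(config$seed, 4L), {
    r <- 5 + 4 * lat + matrix(stats::rnorm(2 * n, 0, config$rating_noise_sd), n, 2)
    pmin(pmax(r, 1), 9)
  })
  manifest$rating_valence <- rate[, 1]
  manifest$rating_arousal <- rate[, 2]
  make_trial <- function(i) {
    row <- manifest[i, ]
    off <- participant_offsets(row$participant, config)
    tr <- generate_trial(config, seed = row$seed,
                         latents = c(valence = row$latent_valence,
                                     arousal = row$latent_arousal),
                         asym_offset = off[["asym"]],
                         beta_offset = off[["beta"]])
    tr$rating_valence <- row$rating_valence
    tr$rating_arousal <- row$rating_arousal
    tr$participant <- row$participant
    tr$trial <- row$trial
    tr
  }
  trials <- if (signals) lapply(seq_len(n), make_trial) else NULL
  list(manifest = manifest, make_trial = make_trial, trials = trials)
}

# Balanced factorial latents: per quadruple one (|v|, |a|) magnitude pair
# in all four sign combinations, shuffled; remainder rows drawn iid. The
# signed products sum to zero within quadruples, so cor(valence, arousal)
# is exactly 0 over complete quadruples.
balanced_latents <- function(n) {
  n4 <- n %/% 4L
  v_mag <- stats::runif(n4, 0.05, 0.7)
  a_mag <- stats::runif(n4, 0.05, 0.7)
  v <- as.vector(outer(c(1, 1, -1, -1), v_mag))
  a <- as.vector(outer(c(1, -1, 1, -1), a_mag))
  if (n %% 4L > 0) {
    extra <- n %% 4L
    v <- c(v, stats::runif(extra, -0.7, 0.7))
    a <- c(a, stats::runif(extra, -0.7, 0.7))
  }
  ord <- sample.int(n)
  cbind(v[ord], a[ord])
}

#' Generate a synthetic scene image
#'
#' `diverse` emulates landscape scenes with natural light: a patchwork of
#' many hues with wide saturation spread. `monotone` emulates indoor or
#' single-tint scenes: a narrow hue range with little saturation variance.
#' `variation = 0` collapses either style to a constant-color image.
#'
#' @param style `"diverse"` or `"monotone"`.
#' @param width,height pixel dimensions (>= 16).
#' @param seed integer seed.
#' @param variation scale in [0, 1] on the within-scene variability.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
generate_scene <- function(style = c("diverse", "monotone"), width = 64,
                           height = 64, seed = 1, variation = 1) {
  style <- match.arg(style)
  if (width < 16 || height < 16) stopf("scene dimensions must be >= 16")
  if (variation < 0 || variation > 1) stopf("variation must lie in [0, 1]")
  nb <- 8L  # patch grid
  with_seed(seed, {
    if (style == "diverse") {
      h <- stats::runif(nb * nb)
      s <- 0.65 + variation * stats::runif(nb * nb, -0.55, 0.35)
      v <- 0.55 + variation * stats::runif(nb * nb, -0.35, 0.4)
    } else {
      h0 <- stats::runif(1)
      h <- (h0 + variation * stats::runif(nb * nb, -0.02, 0.02)) %% 1
      s <- 0.22 + variation * stats::runif(nb * nb, -0.05, 0.05)
      v <- 0.5 + variation * stats::runif(nb * nb, -0.12, 0.12)
    }
    if (variation == 0) { h[] <- h[1]; s[] <- s[1]; v[] <- v[1] }
    up <- function(x) {
      m <- matrix(x, nb, nb)
      m[rep(seq_len(nb), each = ceiling(height / nb))[seq_len(height)],
        rep(seq_len(nb), each = ceiling(width / nb))[seq_len(width)]]
    }
    hsv_to_rgb(list(h = up(h), s = pmin(pmax(up(s), 0), 1),
                    v = pmin(pmax(up(v), 0), 1)))
  })
}
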