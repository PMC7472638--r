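# Session persistence: a flat binary array of doubles plus a JSON sidecar
# describing shape, rate, labels and per-trial metadata, and a CSV dataset
# manifest. (The array+sidecar layout is the documented on-disk form for
# multi-channel sessions; channel labels are stored in DEAP order.)

#' Write EEG trials as a binary array + JSON sidecar
#'
#' The `.bin` file holds the trial matrices as little-endian doubles,
#' concatenated trial by trial in column-major (channel-fastest) order; the
#' `.json` sidecar records dimensions, sampling rate, channel labels and
#' per-trial metadata needed to reconstruct every `eeg_trial`.
#'
#' @param trials list of `eeg_trial` objects with identical shape.
#' @param prefix output path prefix (writes `<prefix>.bin`, `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_session <- function(trials, prefix) {
  if (length(trials) == 0) stopf("no trials to write")
  d <- dim(trials[[1]]$data)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (tr in trials) {
    if (!identical(dim(tr$data), d)) stopf("trials differ in shape")
    writeBin(as.vector(tr$data), con, size = 8, endian = "little")
  }
  meta <- list(
    n_trials = length(trials), n_channels = d[1], n_samples = d[2],
    fs = trials[[1]]$fs, channel_labels = trials[[1]]$channel_labels,
    baseline_samples = trials[[1]]$baseline_samples,
    trials = lapply(trials, function(tr) list(
      participant = tr$participant, trial = tr$trial, content = tr$content,
      emotion = if (is.null(tr$condition)) NA else tr$condition$emotion,
      contrast = if (is.null(tr$condition)) NA else tr$condition$contrast,
      rating_valence = tr$rating_valence, rating_arousal = tr$rating_arousal,
      latent_valence = tr$latent_valence, latent_arousal = tr$latent_arousal
    ))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read EEG trials written by [write_session()]
#'
#' @param prefix path prefix used when writing.
#' @return list of `eeg_trial` objects.
#' @export
read_session <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = FALSE)
  nc <- meta$n_channels; ns <- meta$n_samples
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  lapply(seq_len(meta$n_trials), function(i) {
    x <- readBin(con, "double", n = nc * ns, size = 8, endian = "little")
    info <- meta$trials[[i]]
    cond <- if (is.null(info$emotion) || is.na(info$emotion)) NULL
            else list(emotion = info$emotion, contrast = info$contrast)
    structure(list(
      data = matrix(x, nc, ns), fs = meta$fs,
      channel_labels = unlist(meta$channel_labels),
      condition = cond,
      rating_valence = info$rating_valence,
      rating_arousal = info$rating_arousal,
      latent_valence = info$latent_valence,
      latent_arousal = info$latent_arousal,
      baseline_samples = meta$baseline_samples,
      participant = info$participant, trial = info$trial,
      content = info$content
    ), class = "eeg_trial")
  })
}

#' Write a dataset manifest CSV
#'
#' One row per trial: participant, trial, condition, ratings and latent
#' ground truth.
#'
#' @param trials list of `eeg_trial` objects or a manifest data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(trials, path) {
  df <- if (is.data.frame(trials)) trials else
    do.call(rbind, lapply(trials, function(tr) data.frame(
      participant = tr$participant %||% NA, trial = tr$trial %||% NA,
      content = tr$content %||% NA,
      emotion = if (is.null(tr$condition)) NA else tr$condition$emotion,
      contrast = if (is.null(tr$condition)) NA else tr$condition$contrast,
      rating_valence = tr$rating_valence, rating_arousal = tr$rating_arousal,
      latent_valence = tr$latent_valence, latent_arousal = tr$latent_arousal
    )))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
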