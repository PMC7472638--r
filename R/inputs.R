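# Construction of 32x32 channel-by-time model inputs and the
# participant-level train/validation/test split.

INPUT_SAMPLES <- 7680L
WINDOW <- 32L

#' Inputs per trial for a given column count
#'
#' One model input consumes `k` consecutive non-overlapping 32-sample
#' windows (32 * k samples); inputs tile the 7680-sample trial with stride
#' `32 * k`, giving `floor(7680 / (32 k))` inputs per trial.
#'
#' @param k number of recognizer columns.
#' @param n_samples samples per trial (default 7680).
#' @return integer count.
#' @export
inputs_per_trial <- function(k, n_samples = INPUT_SAMPLES) {
  if (!is_count(k)) stopf("k must be a positive integer")
  as.integer(floor(n_samples / (WINDOW * k)))
}

#' Segment a processed trial into model inputs
#'
#' Input `i` starts at offset `(i - 1) * 32 * k` and stacks `k` consecutive
#' 32-channel x 32-sample windows. When `32 * k` divides 7680 the inputs
#' tile the trial exactly.
#'
#' @param trial a `processed_trial` (32 x 7680 matrix).
#' @param k number of windows (columns) per input.
#' @return list with `windows`, a 32 x 32 x k x n array, `offsets` (0-based
#'   start sample of each input), and the trial's targets.
#' @export
segment_trial <- function(trial, k = 5) {
  if (!is_count(k)) stopf("k must be a positive integer")
  d <- trial$data
  if (nrow(d) != WINDOW || ncol(d) != INPUT_SAMPLES)
    stopf("expected a 32 x 7680 processed trial, got %d x %d", nrow(d), ncol(d))
  n <- inputs_per_trial(k)
  win <- array(0, c(WINDOW, WINDOW, k, n))
  for (i in seq_len(n)) {
    base <- (i - 1L) * WINDOW * k
    for (j in seq_len(k))
      win[, , j, i] <- d[, (base + (j - 1L) * WINDOW + 1L):(base + j * WINDOW)]
  }
  list(
    windows = win,
    offsets = (seq_len(n) - 1L) * WINDOW * k,
    valence_target = map_rating_to_target(trial$rating_valence),
    arousal_target = map_rating_to_target(trial$rating_arousal)
  )
}

#' Map a 1-9 rating to the recognizer's (-1, 1) target scale
#'
#' `target = (rating - 5) / 4`, nudged into the open interval by 1e-6 at the
#' endpoints (the recognizer's tanh output cannot reach +-1).
#'
#' @param rating numeric vector of ratings in [1, 9].
#' @return numeric vector in (-1, 1).
#' @export
map_rating_to_target <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9))
    stopf("ratings must lie in [1, 9]")
  eps <- 1e-6
  pmin(pmax((rating - 5) / 4, -1 + eps), 1 - eps)
}

#' Thin an input set by keeping every m-th input per trial
#'
#' Inputs from the same trial share that trial's injected band powers and
#' ratings, so consecutive inputs are highly redundant for training; a
#' thinned training set trades little information for a proportional cut
#' in epoch cost. Evaluation sets are normally left unthinned.
#'
#' @param set an input set from [make_dataset()] or [prepare_inputs()].
#' @param keep_every keep inputs whose within-trial index is 1 modulo this.
#' @return the thinned input set.
#' @export
thin_inputs <- function(set, keep_every) {
  keep <- which(set$manifest$input %% keep_every == 1L)
  list(x = lapply(set$x, function(m) m[keep, , drop = FALSE]),
       y = set$y[keep, , drop = FALSE],
       manifest = set$manifest[keep, , drop = FALSE],
       n = length(keep), k = set$k)
}

#' Participant-level split specification
#'
#' Assigns participant ids to train/validation/test parts: by default the
#' first `counts[1]` ids train, the next `counts[2]` validate, the last
#' `counts[3]` test; `shuffle_seed` permutes ids first.
#'
#' @param participants vector of participant ids.
#' @param counts length-3 vector of part sizes (default 22/5/5).
#' @param shuffle_seed optional seed for a permuted assignment.
#' @return list with disjoint `train`, `val`, `test` id vectors.
#' @export
split_spec <- function(participants, counts = c(22, 5, 5), shuffle_seed = NULL) {
  participants <- unique(participants)
  if (length(counts) != 3 || sum(counts) != length(participants))
    stopf("split counts %s do not cover the %d participants",
          paste(counts, collapse = "/"), length(participants))
  if (!is.null(shuffle_seed))
    participants <- with_seed(shuffle_seed, sample(participants))
  list(train = participants[seq_len(counts[1])],
       val = participants[counts[1] + seq_len(counts[2])],
       test = participants[counts[1] + counts[2] + seq_len(counts[3])])
}

check_split <- function(split, participants) {
  parts <- c(split$train, split$val, split$test)
  if (anyDuplicated(parts))
    stopf("split parts overlap: participant leakage")
  if (!setequal(parts, unique(participants)))
    stopf("split does not cover every participant exactly once")
  invisible(split)
}

#' Build train/validation/test input sets from processed trials
#'
#' Segments every trial with [segment_trial()] and groups the inputs by the
#' participant-level split. Inputs inherit their trial's rating targets
#' (mapped to (-1, 1)). With `materialize = FALSE` only the manifest and
#' counts are produced, which is how full-size dataset arithmetic is checked
#' without holding gigabytes of windows.
#'
#' @param trials list of `processed_trial` objects (each with
#'   `$participant`), or, when `materialize = FALSE`, a data.frame manifest
#'   with columns participant, trial, rating_valence, rating_arousal.
#' @param split a [split_spec()] over the participants.
#' @param k windows per input (recognizer columns).
#' @param materialize build the window arrays.
#' @return list of three input sets (`train`, `val`, `test`); each has
#'   `x` (list of k matrices, n x 1024, one per column; NULL if not
#'   materialized), `y` (n x 2 targets) and `manifest`.
#' @export
make_dataset <- function(trials, split, k = 5, materialize = TRUE) {
  if (is.data.frame(trials)) {
    if (materialize) stopf("a manifest alone cannot materialize windows")
    manifest <- trials
  } else {
    manifest <- data.frame(
      participant = vapply(trials, function(t) t$participant, 0),
      trial = vapply(trials, function(t) t$trial, 0),
      rating_valence = vapply(trials, function(t) t$rating_valence, 0),
      rating_arousal = vapply(trials, function(t) t$rating_arousal, 0)
    )
  }
  check_split(split, manifest$participant)
  n_in <- inputs_per_trial(k)
  build_part <- function(ids) {
    rows <- which(manifest$participant %in% ids)
    im <- manifest[rep(rows, each = n_in), , drop = FALSE]
    im$input <- rep(seq_len(n_in), length(rows))
    im$offset <- (im$input - 1L) * WINDOW * k
    y <- cbind(valence = map_rating_to_target(im$rating_valence),
               arousal = map_rating_to_target(im$rating_arousal))
    x <- NULL
    if (materialize && length(rows)) {
      x <- lapply(seq_len(k), function(j)
        matrix(0, length(rows) * n_in, WINDOW * WINDOW))
      at <- 0L
      for (r in rows) {
        seg <- segment_trial(trials[[r]], k)
        for (i in seq_len(n_in))
          for (j in seq_len(k))
            x[[j]][at + i, ] <- as.vector(seg$windows[, , j, i])
        at <- at + n_in
      }
    } else if (materialize) {
      x <- lapply(seq_len(k), function(j) matrix(0, 0, WINDOW * WINDOW))
    }
    list(x = x, y = y, manifest = im, n = length(rows) * n_in, k = k)
  }
  list(train = build_part(split$train), val = build_part(split$val),
       test = build_part(split$test))
}
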