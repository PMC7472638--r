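# Self-contained experiments over the pipeline: the high-SNR recognizer
# benchmark, the scaled protocol analysis (emotion / contrast t-test
# tables, orderings, ranking), and the null calibration of the group
# t-tests. These are the computations behind the analysis/ drivers and the
# acceptance checks.

#' High-SNR recognizer benchmark on a two-class valence corpus
#'
#' Generates a two-class dataset (latent valence -0.7 / +0.7, balanced) at
#' a large injected valence effect, trains the k = 5 recognizer and a
#' label-shuffled control with identical settings, and reports held-out
#' accuracy and validation losses. Trial-level accuracy averages the fused
#' estimates over each held-out trial's inputs before binarizing at 0.
#'
#' @param seed master seed.
#' @param n_per_class trials per valence class (default 200).
#' @param valence_effect injected asymmetry slope (default 2).
#' @param epochs training epochs for both model and control.
#' @param thin keep every `thin`-th training input per trial (see
#'   [thin_inputs()]); evaluation uses the full tiling.
#' @return list with `accuracy_trial`, `accuracy_input`, `val_loss`,
#'   `shuffled_val_loss`, the metrics table and the split sizes.
#' @export
experiment_high_snr <- function(seed, n_per_class = 200, valence_effect = 2,
                                epochs = 6, thin = 3) {
  n_participants <- 20L
  trials_pp <- as.integer(ceiling(2 * n_per_class / n_participants))
  scfg <- synth_config(n_participants = n_participants,
                       trials_per_participant = trials_pp,
                       valence_effect = valence_effect,
                       seed = derive_seed(seed, 41L))
  ds <- generate_deap_like_dataset(
    scfg,
    latent_sampler = function(n) cbind(rep(c(-0.7, 0.7), length.out = n), 0))
  split <- split_spec(seq_len(n_participants), c(10L, 4L, 6L))
  sets <- prepare_inputs(ds, split, k = 5)
  train_set <- thin_inputs(sets$train, thin)
  val_set <- thin_inputs(sets$val, thin)
  tc <- train_config(epochs = epochs, patience = 3,
                     seed = derive_seed(seed, 43L))
  model <- train(init_model(5, seed = derive_seed(seed, 42L)),
                 train_set, val_set, tc)
  shuffled <- train_set
  shuffled$y <- shuffled$y[with_seed(derive_seed(seed, 44L),
                                     sample.int(nrow(shuffled$y))), ,
                           drop = FALSE]
  control <- train(init_model(5, seed = derive_seed(seed, 42L)),
                   shuffled, val_set, tc)
  pred <- predict_inputs(model, sets$test)
  truth <- sets$test$y[, "valence"] > 0
  acc_input <- mean((pred[, "valence"] > 0) == truth)
  trial_id <- paste(sets$test$manifest$participant, sets$test$manifest$trial)
  trial_pred <- tapply(pred[, "valence"], trial_id, mean)
  trial_truth <- tapply(sets$test$y[, "valence"], trial_id, mean) > 0
  acc_trial <- mean((trial_pred > 0) == trial_truth[names(trial_pred)])
  list(
    accuracy_trial = unname(acc_trial),
    accuracy_input = unname(acc_input),
    val_loss = min(model$history$val_loss),
    shuffled_val_loss = min(control$history$val_loss),
    metrics = evaluate(model, sets$test),
    n_trials = nrow(ds$manifest),
    n_inputs = vapply(sets, function(s) s$n, 0)
  )
}

#' Scaled protocol analysis run
#'
#' [run_experiment()] at a reduced problem size: a smaller DEAP-shaped
#' training corpus and fewer protocol participants, with generator defaults
#' otherwise (valence effects injected, condition-level arousal null).
#'
#' @param seed master seed.
#' @param n_protocol protocol participants (each contributes one 27-trial
#'   session).
#' @param n_corpus,trials_pp training-corpus dimensions.
#' @param split participant split for the corpus.
#' @param epochs training epochs.
#' @return the [run_experiment()] report.
#' @export
experiment_protocol <- function(seed, n_protocol = 12, n_corpus = 16,
                                trials_pp = 15, split = c(10L, 3L, 3L),
                                epochs = 8) {
  cfg <- run_config(
    seed = seed,
    synth = list(n_participants = as.integer(n_corpus),
                 trials_per_participant = as.integer(trials_pp)),
    split = as.integer(split),
    train = list(epochs = epochs),
    input_thin = 3L,
    n_protocol_participants = as.integer(n_protocol))
  suppressMessages(run_experiment(cfg))
}

#' Null calibration of the group t-tests
#'
#' With both effect sizes at zero, repeatedly generates two groups of
#' trials from distinct participants, measures the frontal alpha asymmetry
#' of each trial, and Welch-tests the groups. Under this null the injected
#' asymmetry is pure Gaussian trial noise, so the p values are exactly
#' calibrated; the fraction rejected at `alpha` estimates the type-I rate.
#'
#' @param seed master seed.
#' @param n_reps replicates (default 500).
#' @param n_per_group trials per group.
#' @param alpha significance threshold (default 0.01).
#' @return list with `rate`, `rejections`, `n_reps`.
#' @export
experiment_null_calibration <- function(seed, n_reps = 500, n_per_group = 6,
                                        alpha = 0.01) {
  cfg <- synth_config(valence_effect = 0, arousal_effect = 0,
                      asym_participant_sd = 0, beta_participant_sd = 0,
                      content_duration = 5, baseline_duration = 0.5,
                      fs_raw = 128, n_channels_total = 32,
                      seed = derive_seed(seed, 61L))
  rej <- 0L
  for (r in seq_len(n_reps)) {
    asym <- vapply(seq_len(2 * n_per_group), function(i)
      alpha_asymmetry(generate_trial(
        cfg, seed = derive_seed(cfg$seed, r, i),
        latents = c(valence = 0, arousal = 0))), 0)
    res <- welch_ttest(asym[seq_len(n_per_group)],
                       asym[n_per_group + seq_len(n_per_group)],
                       alpha = alpha)
    if (res$p < alpha) rej <- rej + 1L
  }
  list(rate = rej / n_reps, rejections = rej, n_reps = n_reps)
}
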