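# End-to-end orchestration: scenes -> contrast -> synthetic EEG ->
# preprocessing -> inputs -> training -> trial prediction -> condition
# statistics, as one reproducible run.

#' Default run configuration
#'
#' Houses the study constants (contrast alphas +-0.1, k = 5 columns, band
#' 4-45 Hz at 128 Hz, 22/5/5 participant split) plus the synthetic-data and
#' training settings. Any field can be overridden through
#' [validate_config()] or the `...` arguments here.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param ... named overrides of the default fields.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    alpha_up = 0.1, alpha_down = -0.1,
    k = 5L,
    low = 4, high = 45, fs_target = 128,
    split = c(22L, 5L, 5L),
    synth = list(),                     # overrides for synth_config()
    train = list(epochs = 8, batch_size = 64, lr = 1e-3, patience = 3),
    input_thin = 1L,
    n_protocol_participants = 30L,
    scene_styles = c("diverse", "diverse", "diverse"),
    scene_size = 64L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.finite(cfg$alpha_up) || !is.finite(cfg$alpha_down))
    stopf("contrast alphas must be finite numbers")
  if (!is_count(cfg$k)) stopf("k must be a positive integer")
  if (length(cfg$split) != 3 || any(cfg$split < 0))
    stopf("split must be three nonnegative counts")
  if (!(0 < cfg$low && cfg$low < cfg$high && cfg$high < cfg$fs_target / 2))
    stopf("band [%g, %g] infeasible at %g Hz", cfg$low, cfg$high, cfg$fs_target)
  bad <- setdiff(names(cfg$synth), names(formals(synth_config)))
  if (length(bad)) stopf("unknown synth keys: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$train), names(formals(train_config)))
  if (length(bad)) stopf("unknown train keys: %s", paste(bad, collapse = ", "))
  for (f in c("epochs", "batch_size", "lr", "patience"))
    if (!is.null(cfg$train[[f]]) && !is.numeric(cfg$train[[f]]))
      stopf("train$%s must be numeric", f)
  class(cfg) <- "run_config"
  cfg
}

#' Load and validate a run configuration from a YAML file
#'
#' Unknown keys are rejected with the offending names; an empty file yields
#' the full default configuration (alphas +-0.1, k = 5, band 4-45 Hz,
#' 128 Hz, 22/5/5 split).
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stopf("config must be a YAML mapping")
  do.call(run_config, c(list(seed = raw$seed %||% 1),
                        raw[setdiff(names(raw), "seed")]))
}

synth_for_run <- function(cfg, ...) {
  args <- cfg$synth
  over <- list(...)
  args[names(over)] <- over
  if (is.null(args$seed)) args$seed <- derive_seed(cfg$seed, 11L)
  args$fs_target <- cfg$fs_target
  do.call(synth_config, args)
}

#' Stream a rated dataset through preprocessing into input sets
#'
#' For every trial in the dataset manifest: generate the raw waveform,
#' preprocess it (downsample, band-pass, channel selection, baseline trim),
#' segment it into k-window inputs, and collect the inputs by the
#' participant split. Only the finished 32x32 windows are held in memory,
#' never the raw corpus.
#'
#' @param dataset a [generate_deap_like_dataset()] result (manifest +
#'   `make_trial`).
#' @param split a [split_spec()] over the corpus participants.
#' @param k windows per input.
#' @param fs_target,low,high preprocessing parameters.
#' @return list of train/val/test input sets as in [make_dataset()].
#' @export
prepare_inputs <- function(dataset, split, k = 5, fs_target = 128,
                           low = 4, high = 45) {
  manifest <- dataset$manifest
  check_split(split, manifest$participant)
  n_in <- inputs_per_trial(k)
  part_of <- function(p) if (p %in% split$train) "train"
    else if (p %in% split$val) "val" else "test"
  sets <- list()
  for (part in c("train", "val", "test")) {
    rows <- which(vapply(manifest$participant, part_of, "") == part)
    n <- length(rows) * n_in
    x <- lapply(seq_len(k), function(j) matrix(0, n, 1024L))
    y <- matrix(0, n, 2, dimnames = list(NULL, c("valence", "arousal")))
    im <- manifest[rep(rows, each = n_in), , drop = FALSE]
    im$input <- rep(seq_len(n_in), length(rows))
    im$offset <- (im$input - 1L) * 32L * k
    at <- 0L
    for (r in rows) {
      tr <- preprocess_trial(dataset$make_trial(r), fs_target, low, high)
      seg <- segment_trial(tr, k)
      for (i in seq_len(n_in)) {
        for (j in seq_len(k))
          x[[j]][at + i, ] <- as.vector(seg$windows[, , j, i])
        y[at + i, ] <- c(seg$valence_target, seg$arousal_target)
      }
      at <- at + n_in
    }
    sets[[part]] <- list(x = x, y = y, manifest = im, n = n, k = k)
  }
  sets
}

#' Run the full experiment
#'
#' Executes every stage in order: synthetic scene generation and contrast
#' reports at the configured alphas; DEAP-shaped training corpus ->
#' preprocessing -> input construction under the participant split ->
#' recognizer training and evaluation; protocol sessions for the experiment
#' participants -> trial-level decoding; and the condition statistics
#' (emotion and contrast t-test tables, ordering checks, content ranking).
#' The scene contrast deltas scale each content's contrast-driven latent
#' shift, so color-diverse contents change more than monotone ones. The
#' report is identical for identical (config, seed).
#'
#' @param config a `run_config`.
#' @param out_dir optional directory for the report bundle (report.json +
#'   tables/*.csv).
#' @return report list with sections `dataset`, `model`, `predictions`,
#'   `stats`, `contrast`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- validate_run_config(config)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  scenes <- stage("scenes", {
    lapply(seq_along(cfg$scene_styles), function(i)
      generate_scene(cfg$scene_styles[i], cfg$scene_size, cfg$scene_size,
                     seed = derive_seed(cfg$seed, 21L, i)))
  })
  reports <- stage("contrast", {
    lapply(scenes, function(sc)
      contrast_report(sc, adjust_contrast(sc, cfg$alpha_up)))
  })
  names(reports) <- as.character(seq_along(reports))
  deltas <- vapply(reports, function(r) r$contrast_delta, 0)
  gains <- deltas / mean(deltas)

  scfg <- synth_for_run(cfg)
  dataset <- stage("synthgen", generate_deap_like_dataset(scfg))
  split <- split_spec(unique(dataset$manifest$participant), cfg$split)
  sets <- stage("inputs", prepare_inputs(dataset, split, cfg$k,
                                         cfg$fs_target, cfg$low, cfg$high))
  counts <- list(
    trials = vapply(list(split$train, split$val, split$test), function(ids)
      sum(dataset$manifest$participant %in% ids), 0),
    inputs = vapply(sets, function(s) s$n, 0),
    inputs_per_trial = inputs_per_trial(cfg$k),
    session_trials = 27L
  )

  model <- stage("train", {
    m <- init_model(cfg$k, seed = derive_seed(cfg$seed, 31L))
    tc <- do.call(train_config, c(cfg$train,
                                  list(seed = derive_seed(cfg$seed, 32L))))
    tr_set <- if (cfg$input_thin > 1) thin_inputs(sets$train, cfg$input_thin)
              else sets$train
    va_set <- if (cfg$input_thin > 1) thin_inputs(sets$val, cfg$input_thin)
              else sets$val
    train(m, tr_set, va_set, tc)
  })
  metrics <- stage("evaluate", evaluate(model, sets$test))

  predictions <- stage("predict", {
    rows <- list()
    for (p in seq_len(cfg$n_protocol_participants)) {
      session <- generate_session(p, scfg, contrast_gains = gains)
      for (tr in session) {
        pt <- preprocess_trial(tr, cfg$fs_target, cfg$low, cfg$high)
        est <- predict_trial(model, pt)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, content = tr$content,
          emotion = tr$condition$emotion, contrast = tr$condition$contrast,
          valence = est[["valence"]], arousal = est[["arousal"]])
      }
    }
    do.call(rbind, rows)
  })

  stats_out <- stage("stats", {
    scores <- aggregate_scores(predictions)
    list(scores = scores,
         emotions = compare_emotions(scores),
         contrast = compare_contrast(scores),
         ordering = ordering_check(scores),
         ranking = rank_by_change(scores, reports))
  })

  report <- list(
    config = unclass(cfg),
    dataset = counts,
    contrast = list(reports = reports, gains = as.list(gains)),
    model = list(history = model$history, test_metrics = metrics),
    predictions = predictions,
    stats = stats_out
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  for (nm in c("emotions", "contrast", "ordering", "ranking", "scores"))
    utils::write.csv(report$stats[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$predictions,
                   file.path(out_dir, "tables", "predictions.csv"),
                   row.names = FALSE)
  slim <- report
  slim$predictions <- NULL
  slim$stats$scores <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  invisible(out_dir)
}
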