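# The synthetic EEG generator: determinism, protocol structure, injected
# spectral effects, scenes, and session persistence.

test_that("identical config and seed give bit-identical trials", {
  cfg <- fast_cfg()
  a <- generate_trial(cfg, seed = 42, latents = c(valence = 0.3, arousal = -0.2))
  b <- generate_trial(cfg, seed = 42, latents = c(valence = 0.3, arousal = -0.2))
  expect_identical(a$data, b$data)
  expect_identical(a$rating_valence, b$rating_valence)
  c <- generate_trial(cfg, seed = 43, latents = c(valence = 0.3, arousal = -0.2))
  expect_gt(max(abs(a$data - c$data)), 0)
})

test_that("trial dimensions, ratings and validation follow the config", {
  cfg <- fast_cfg()
  tr <- generate_trial(cfg, seed = 1, condition = list(emotion = "neutral",
                                                       contrast = "original"))
  expect_equal(dim(tr$data), c(32, 128 * 9))
  expect_equal(tr$baseline_samples, 128)
  expect_true(tr$rating_valence >= 1 && tr$rating_valence <= 9)
  expect_error(generate_trial(cfg, 1, latents = c(valence = 1.2, arousal = 0)),
               "latent")
  expect_error(synth_config(fs_raw = 64), "fs_raw")
  expect_error(synth_config(valence_effect = -1), "effect")
})

test_that("emotion and contrast conditions map to the documented latents", {
  cfg <- fast_cfg()
  lat <- function(emo, ctr) generate_trial(
    cfg, 1, condition = list(emotion = emo, contrast = ctr))$latent_valence
  expect_equal(lat("negative", "original"), -0.7)
  expect_equal(lat("neutral", "original"), 0)
  expect_equal(lat("positive", "original"), 0.7)
  expect_equal(lat("neutral", "up"), 0.15)
  expect_equal(lat("neutral", "down"), -0.15)
  # contrast shifts valence only
  tr <- generate_trial(cfg, 1, condition = list(emotion = "positive",
                                                contrast = "up"))
  expect_equal(tr$latent_arousal, 0)
})

test_that("injected alpha asymmetry is recovered by a band-power regression", {
  cfg <- fast_cfg(valence_effect = 2, asym_noise_sd = 0.05,
                  content_duration = 10)
  lat <- seq(-0.9, 0.9, length.out = 50)
  asym <- vapply(seq_along(lat), function(i)
    alpha_asymmetry(generate_trial(cfg, seed = 100 + i,
                                   latents = c(valence = lat[i], arousal = 0))),
    0)
  slope <- stats::coef(stats::lm(asym ~ lat))[[2]]
  expect_lt(abs(slope - 2) / 2, 0.2)
})

test_that("injected beta power tracks latent arousal", {
  cfg <- fast_cfg(arousal_effect = 1.5, beta_noise_sd = 0.05,
                  content_duration = 10)
  lat <- seq(-0.9, 0.9, length.out = 30)
  bp <- vapply(seq_along(lat), function(i)
    beta_log_power(generate_trial(cfg, seed = 300 + i,
                                  latents = c(valence = 0, arousal = lat[i]))),
    0)
  slope <- stats::coef(stats::lm(bp ~ lat))[[2]]
  expect_lt(abs(slope - 1.5) / 1.5, 0.2)
})

test_that("a session is 27 trials covering each condition three times", {
  cfg <- fast_cfg()
  session <- generate_session(7, cfg)
  expect_length(session, 27)
  cond <- table(vapply(session, function(tr)
    paste(tr$condition$emotion, tr$condition$contrast), ""))
  expect_equal(length(cond), 9)
  expect_true(all(cond == 3))
  expect_true(all(vapply(session, function(tr)
    tr$baseline_samples == cfg$fs_raw * cfg$baseline_duration, TRUE)))
  # the three contrast blocks appear in protocol order
  ctr <- vapply(session, function(tr) tr$condition$contrast, "")
  expect_equal(unique(ctr), c("original", "up", "down"))
  expect_equal(rle(ctr)$lengths, c(9, 9, 9))
})

test_that("the DEAP-shaped dataset ties ratings to latents on both sides of 5", {
  cfg <- fast_cfg(n_participants = 6, trials_per_participant = 10)
  ds <- generate_deap_like_dataset(cfg)
  expect_equal(nrow(ds$manifest), 60)
  expect_true(any(ds$manifest$rating_valence > 5) &&
                any(ds$manifest$rating_valence < 5))
  expect_gt(stats::cor(ds$manifest$latent_valence, ds$manifest$rating_valence),
            0.9)
  # materialized trials agree with the manifest and the constructor
  tr <- ds$make_trial(13)
  expect_identical(tr$data, ds$make_trial(13)$data)
  expect_equal(tr$participant, ds$manifest$participant[13])
  # custom latent sampler supports two-class designs
  two <- generate_deap_like_dataset(
    fast_cfg(n_participants = 2, trials_per_participant = 4),
    latent_sampler = function(n) cbind(rep(c(-0.7, 0.7), length.out = n), 0))
  expect_setequal(unique(two$manifest$latent_valence), c(-0.7, 0.7))
})

test_that("scene styles separate by saturation spread and contrast response", {
  div <- generate_scene("diverse", 48, 48, seed = 21)
  mono <- generate_scene("monotone", 48, 48, seed = 21)
  sat_sd <- function(img) stats::sd(rgb_to_hsv(img)$s)
  expect_gt(sat_sd(div), sat_sd(mono))
  # a zero-variation scene is constant color: the operator is a no-op
  flat <- generate_scene("monotone", 32, 32, seed = 3, variation = 0)
  expect_lt(max(abs(adjust_contrast(flat, 0.1) - flat)), 1e-6)
  # contrast control changes diverse scenes more than monotone ones
  d_div <- contrast_report(div, adjust_contrast(div, 0.1))$contrast_delta
  d_mono <- contrast_report(mono, adjust_contrast(mono, 0.1))$contrast_delta
  expect_gt(abs(d_div), abs(d_mono))
  expect_error(generate_scene("diverse", 8, 32), ">= 16")
})

test_that("session persistence round-trips through the array + sidecar layout", {
  cfg <- fast_cfg(content_duration = 2, baseline_duration = 0.5)
  trials <- lapply(1:3, function(i)
    generate_trial(cfg, seed = i, condition = list(emotion = "positive",
                                                   contrast = "down")))
  trials <- lapply(seq_along(trials), function(i) {
    trials[[i]]$participant <- 1; trials[[i]]$trial <- i; trials[[i]]
  })
  prefix <- tempfile()
  write_session(trials, prefix)
  back <- read_session(prefix)
  expect_length(back, 3)
  expect_equal(back[[2]]$data, trials[[2]]$data)
  expect_equal(back[[2]]$condition, trials[[2]]$condition)
  expect_equal(back[[3]]$rating_valence, trials[[3]]$rating_valence)
  manifest_path <- tempfile(fileext = ".csv")
  write_manifest(trials, manifest_path)
  mf <- utils::read.csv(manifest_path)
  expect_equal(nrow(mf), 3)
  expect_equal(mf$emotion, rep("positive", 3))
  unlink(c(paste0(prefix, c(".bin", ".json")), manifest_path))
})
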