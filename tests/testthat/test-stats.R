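# Welch t-tests, aggregation, condition comparisons, orderings, ranking.

# Independent hand-coded Welch-Satterthwaite implementation used as the
# oracle against the package's test.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Synthetic score table: per-participant condition means with fixed cell
# means, for the comparison and ordering tests.
score_table <- function(cell_means, n = 8, sd = 0.02, seed = 1,
                        contents = 1:3) {
  eegcontrast:::with_seed(seed, {
    rows <- list()
    for (content in contents)
      for (emotion in c("negative", "neutral", "positive"))
        for (contrast in c("down", "original", "up")) {
          mu <- cell_means(content, emotion, contrast)
          rows[[length(rows) + 1]] <- data.frame(
            participant = seq_len(n), content = content, emotion = emotion,
            contrast = contrast,
            valence = mu[1] + stats::rnorm(n, 0, sd),
            arousal = mu[2] + stats::rnorm(n, 0, sd))
        }
    do.call(rbind, rows)
  })
}

latent_cells <- function(content, emotion, contrast) {
  v <- c(negative = -0.7, neutral = 0, positive = 0.7)[[emotion]] +
    c(down = -0.15, original = 0, up = 0.15)[[contrast]]
  c(v, 0)
}

test_that("welch test agrees with the hand-coded Satterthwaite oracle", {
  a <- c(2.1, 2.5, 1.9, 2.3)
  b <- c(1.1, 1.4, 0.9, 1.2)
  r <- welch_ttest(a, b)
  o <- welch_oracle(a, b)
  expect_equal(r$t, o$t, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)
  expect_gt(r$t, 5.9)
  # across 100 random pairs
  eegcontrast:::with_seed(31, for (i in 1:100) {
    x <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, -1, 1))
    r <- welch_ttest(x, y)
    o <- welch_oracle(x, y)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  })
})

test_that("welch test handles identity, separation and degenerate input", {
  s <- c(1, 2, 3, 4, 5)
  same <- welch_ttest(s, s)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- welch_ttest(s, s + 10)
  expect_lt(far$p, 0.01)
  expect_true(far$significant)
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
  expect_error(welch_ttest(c(1, 1, 1), c(2, 2, 2)), "degenerate|constant")
  # Student variant is exposed by flag
  st <- welch_ttest(s, s + 1, var_equal = TRUE)
  expect_equal(st$df, 8)
})

test_that("p values are symmetric under swap and invariant to shift and scale", {
  eegcontrast:::with_seed(32, for (i in 1:20) {
    a <- stats::rnorm(6); b <- stats::rnorm(8, mean = 0.5)
    r1 <- welch_ttest(a, b); r2 <- welch_ttest(b, a)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$t, -r2$t)
    r3 <- welch_ttest(a + 3, b + 3)
    expect_equal(r1$p, r3$p, tolerance = 1e-12)
    r4 <- welch_ttest(a * 2.5, b * 2.5)
    expect_equal(r1$p, r4$p, tolerance = 1e-12)
  })
})

test_that("aggregation averages trials within participant-condition cells", {
  pred <- data.frame(
    participant = c(1, 1, 1), content = 1, emotion = "neutral",
    contrast = c("original", "original", "up"),
    valence = c(0.2, 0.4, 0.9), arousal = c(0, 0.2, 0.1))
  sc <- aggregate_scores(pred)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$valence[sc$contrast == "original"], 0.3)
  expect_equal(sc$arousal[sc$contrast == "original"], 0.1)
  # full design arithmetic: 10 participants x 9 conditions x 3 contents
  tbl <- score_table(latent_cells, n = 10)
  expect_equal(nrow(aggregate_scores(tbl)), 270)
  expect_error(aggregate_scores(pred[, -5]), "columns")
})

test_that("emotion and contrast comparisons separate signal from null", {
  tbl <- score_table(latent_cells, n = 10, sd = 0.03, seed = 2)
  sc <- aggregate_scores(tbl)
  emo <- compare_emotions(sc)
  expect_equal(nrow(emo), 12)
  expect_true(all(emo$significant[emo$dimension == "valence"]))
  expect_false(any(emo$significant[emo$dimension == "arousal"]))
  ctr <- compare_contrast(sc)
  expect_equal(nrow(ctr), 36)
  expect_true(all(ctr$significant[ctr$dimension == "valence"]))
  expect_false(any(ctr$significant[ctr$dimension == "arousal"]))
  expect_true(all(ctr$p_bonferroni >= ctr$p))
  # identical score lists give p = 1
  flat <- score_table(function(...) c(0.3, 0), n = 6, sd = 0, seed = 3)
  fe <- compare_emotions(aggregate_scores(flat))
  expect_true(all(fe$p == 1))
  expect_error(compare_emotions(sc[sc$emotion != "neutral", ]), "no scores")
})

test_that("ordering checks report whether shifted valence crosses classes", {
  sc <- aggregate_scores(score_table(latent_cells, n = 8, sd = 0.02, seed = 4))
  ord <- ordering_check(sc)
  expect_equal(nrow(ord), 9)
  expect_true(all(ord$holds))
  # a contrast shift larger than the emotion gap violates the orderings
  big_shift <- function(content, emotion, contrast) {
    v <- c(negative = -0.2, neutral = 0, positive = 0.2)[[emotion]] +
      c(down = -0.5, original = 0, up = 0.5)[[contrast]]
    c(v, 0)
  }
  ord2 <- ordering_check(aggregate_scores(score_table(big_shift, seed = 5)))
  expect_false(any(ord2$holds))
  # equal means everywhere: orderings reported false, not an error
  ord3 <- ordering_check(aggregate_scores(
    score_table(function(...) c(0, 0), sd = 0, seed = 6)))
  expect_false(any(ord3$holds))
})

test_that("contents rank by absolute valence change with stable ties", {
  gains <- c(`1` = 0.3, `2` = 0.1, `3` = 0.3)
  cells <- function(content, emotion, contrast) {
    shift <- c(down = -1, original = 0, up = 1)[[contrast]]
    c(shift * gains[[as.character(content)]], 0)
  }
  sc <- aggregate_scores(score_table(cells, sd = 0, seed = 7))
  rk <- rank_by_change(sc)
  expect_equal(rk$content, c(1, 3, 2))   # tie between 1 and 3 broken by id
  expect_equal(rk$valence_change[3], 0.2, tolerance = 1e-12)
  expect_error(rank_by_change(sc[sc$content == 1, ]), "at least 2")
})

test_that("color-diverse contents change more than monotone ones end to end", {
  # scenes -> contrast gains -> sessions -> asymmetry-based decoding
  styles <- c("diverse", "diverse", "monotone")
  scenes <- lapply(1:3, function(i)
    generate_scene(styles[i], 48, 48, seed = 40 + i))
  reports <- lapply(scenes, function(sc)
    contrast_report(sc, adjust_contrast(sc, 0.1)))
  names(reports) <- 1:3
  deltas <- vapply(reports, function(r) r$contrast_delta, 0)
  gains <- deltas / mean(deltas)
  cfg <- fast_cfg(content_duration = 6, seed = 77)
  rows <- list()
  for (p in 1:6) {
    session <- generate_session(p, cfg, contrast_gains = gains)
    for (tr in session)
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, content = tr$content,
        emotion = tr$condition$emotion, contrast = tr$condition$contrast,
        valence = alpha_asymmetry(tr) / cfg$valence_effect, arousal = 0)
  }
  sc <- aggregate_scores(do.call(rbind, rows))
  rk <- rank_by_change(sc, reports)
  # the monotone content (3) has the smallest contrast delta and ranks last
  expect_equal(rk$content[3], 3)
  expect_equal(order(-rk$contrast_delta), order(-rk$valence_change))
})
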