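# Condition comparisons: per-participant aggregation of decoded valence /
# arousal, Welch t-tests between emotion and contrast conditions, the
# ordering checks (shifted valence never crosses the adjacent original
# emotion), and the ranking of scenes by valence change.

#' Aggregate trial-level estimates to condition scores
#'
#' Means of decoded valence and arousal per participant x content x
#' (emotion, contrast) cell.
#'
#' @param predictions data.frame with columns participant, content, emotion,
#'   contrast, valence, arousal (one row per trial).
#' @return data.frame of per-participant condition means.
#' @export
aggregate_scores <- function(predictions) {
  need <- c("participant", "content", "emotion", "contrast", "valence", "arousal")
  if (!all(need %in% names(predictions)))
    stopf("predictions must have columns: %s", paste(need, collapse = ", "))
  stats::aggregate(cbind(valence, arousal) ~ participant + content +
                     emotion + contrast, data = predictions, FUN = mean)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test between two independent score samples,
#' with significance called at 0.01. `var_equal = TRUE` gives the pooled
#' Student variant.
#'
#' @param a,b numeric samples, each of length >= 2 with nonzero variance.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @param alpha significance threshold (default 0.01).
#' @return list with `t`, `df`, `p`, `significant`.
#' @export
welch_ttest <- function(a, b, var_equal = FALSE, alpha = 0.01) {
  if (length(a) < 2 || length(b) < 2) stopf("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1, significant = FALSE))
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stopf("degenerate samples: both have zero variance")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

ttest_row <- function(a, b, pair, dimension, content = NA, emotion = NA,
                      alpha = 0.01, var_equal = FALSE) {
  r <- welch_ttest(a, b, var_equal = var_equal, alpha = alpha)
  data.frame(content = content, emotion = emotion, pair = pair,
             dimension = dimension, t = r$t, df = r$df, p = r$p,
             significant = r$significant)
}

score_cell <- function(scores, content, emotion, contrast, dim) {
  v <- scores[scores$content == content & scores$emotion == emotion &
                scores$contrast == contrast, dim]
  if (length(v) == 0)
    stopf("no scores for content %s, %s/%s", content, emotion, contrast)
  v
}

#' Emotion comparisons at original contrast
#'
#' For each content, Welch tests of neutral vs positive and neutral vs
#' negative per-participant means, on both valence and arousal: 12 results.
#' A Bonferroni-adjusted p column is added alongside the raw p values.
#'
#' @param scores output of [aggregate_scores()].
#' @param alpha significance threshold.
#' @return data.frame of t-test rows.
#' @export
compare_emotions <- function(scores, alpha = 0.01) {
  out <- list()
  for (content in sort(unique(scores$content)))
    for (pair in list(c("neutral", "positive"), c("neutral", "negative")))
      for (dim in c("valence", "arousal")) {
        a <- score_cell(scores, content, pair[1], "original", dim)
        b <- score_cell(scores, content, pair[2], "original", dim)
        out[[length(out) + 1]] <- ttest_row(
          a, b, paste(pair, collapse = " vs "), dim, content, alpha = alpha)
      }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}

#' Contrast comparisons within each emotion
#'
#' For each content x emotion, Welch tests of original vs contrast-up and
#' original vs contrast-down per-participant means, on both valence and
#' arousal: 36 results.
#'
#' @param scores output of [aggregate_scores()].
#' @param alpha significance threshold.
#' @return data.frame of t-test rows.
#' @export
compare_contrast <- function(scores, alpha = 0.01) {
  out <- list()
  for (content in sort(unique(scores$content)))
    for (emotion in c("neutral", "positive", "negative"))
      for (ctr in c("up", "down"))
        for (dim in c("valence", "arousal")) {
          a <- score_cell(scores, content, emotion, "original", dim)
          b <- score_cell(scores, content, emotion, ctr, dim)
          out[[length(out) + 1]] <- ttest_row(
            a, b, paste("original vs", ctr), dim, content, emotion,
            alpha = alpha)
        }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}

#' Ordering check: shifted valence stays within the adjacent emotion
#'
#' Per content, checks three mean-valence orderings: neutral contrast-up
#' below positive original; positive contrast-down above neutral original;
#' negative contrast-up below neutral original. Violations are reported, not
#' errors.
#'
#' @param scores output of [aggregate_scores()].
#' @return data.frame with one row per content x ordering and a logical
#'   `holds` column.
#' @export
ordering_check <- function(scores) {
  mv <- function(content, emotion, contrast)
    mean(score_cell(scores, content, emotion, contrast, "valence"))
  out <- list()
  for (content in sort(unique(scores$content))) {
    checks <- list(
      list(name = "neutral_up_below_positive",
           holds = mv(content, "neutral", "up") < mv(content, "positive", "original")),
      list(name = "positive_down_above_neutral",
           holds = mv(content, "positive", "down") > mv(content, "neutral", "original")),
      list(name = "negative_up_below_neutral",
           holds = mv(content, "negative", "up") < mv(content, "neutral", "original"))
    )
    for (ch in checks)
      out[[length(out) + 1]] <- data.frame(content = content,
                                           ordering = ch$name,
                                           holds = ch$holds)
  }
  do.call(rbind, out)
}

#' Rank contents by contrast-driven valence change
#'
#' Contents sorted by the absolute difference between their mean
#' contrast-up and contrast-down valence (largest first; ties broken by
#' content id). Optional contrast reports attach each content's
#' contrast-metric change, linking valence change to scene color diversity.
#'
#' @param scores output of [aggregate_scores()].
#' @param contrast_reports optional named list of [contrast_report()]
#'   results, one per content id.
#' @return data.frame ranked by `valence_change`.
#' @export
rank_by_change <- function(scores, contrast_reports = NULL) {
  contents <- sort(unique(scores$content))
  if (length(contents) < 2) stopf("ranking needs at least 2 contents")
  rows <- lapply(contents, function(content) {
    up <- mean(do.call(c, lapply(c("neutral", "positive", "negative"),
      function(e) score_cell(scores, content, e, "up", "valence"))))
    dn <- mean(do.call(c, lapply(c("neutral", "positive", "negative"),
      function(e) score_cell(scores, content, e, "down", "valence"))))
    data.frame(content = content, valence_change = abs(up - dn))
  })
  res <- do.call(rbind, rows)
  if (!is.null(contrast_reports)) {
    res$contrast_delta <- vapply(as.character(res$content), function(id) {
      rep <- contrast_reports[[id]]
      if (is.null(rep)) NA_real_ else rep$contrast_delta
    }, 0)
  }
  res[order(-res$valence_change, res$content), , drop = FALSE]
}
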