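# HSV conversions, the linear contrast operator and its change metrics.

test_that("hexcone conversions match definitional values and round-trip", {
  red <- array(c(1, 0, 0), c(1, 1, 3))
  h <- rgb_to_hsv(red)
  expect_equal(c(h$h, h$s, h$v), c(0, 1, 1))
  for (g in c(0, 0.25, 0.7, 1)) {
    gray <- array(g, c(1, 1, 3))
    hg <- rgb_to_hsv(gray)
    expect_equal(c(hg$s, hg$v), c(0, g))
  }
  img <- midrange_image(seed = 3)
  back <- hsv_to_rgb(rgb_to_hsv(img))
  expect_lt(max(abs(back - img)), 1e-6)
  expect_error(rgb_to_hsv(array(2, c(1, 1, 3))), "0, 1")
})

test_that("contrast formula moves saturation by (S - S_avg) * alpha", {
  # 10 pixels whose S plane has mean 0.5 and one pixel at 0.8
  s_vals <- c(0.8, 0.2, rep(0.5, 8))
  hsv <- list(h = matrix(0.25, 2, 5), s = matrix(s_vals, 2, 5),
              v = matrix(0.6, 2, 5))
  img <- hsv_to_rgb(hsv)
  for (case in list(c(0.1, 0.83), c(-0.1, 0.77))) {
    out <- rgb_to_hsv(adjust_contrast(img, case[1]))
    expect_equal(out$s[1, 1], case[2], tolerance = 1e-6)
  }
})

test_that("alpha = 0 is the identity and constant images are fixed points", {
  img <- midrange_image(seed = 4)
  expect_lt(max(abs(adjust_contrast(img, 0) - img)), 1e-6)
  const <- hsv_to_rgb(list(h = matrix(0.6, 3, 4), s = matrix(0.4, 3, 4),
                           v = matrix(0.5, 3, 4)))
  for (a in c(-0.5, 0.1, 2))
    expect_lt(max(abs(adjust_contrast(const, a) - const)), 1e-6)
})

test_that("plane means are preserved exactly without clipping", {
  x <- eegcontrast:::with_seed(5, stats::runif(200, 0.2, 0.8))
  for (a in c(-0.2, 0.1, 0.3)) {
    y <- eegcontrast:::adjust_plane(x, a)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(mean(y), mean(x), tolerance = 1e-12)
  }
  # with clipping the mean shift is bounded by the clipped mass
  x2 <- c(0.98, stats::runif(99, 0.3, 0.7))
  a <- 0.5
  raw <- x2 + (x2 - mean(x2)) * a
  y2 <- eegcontrast:::adjust_plane(x2, a)
  expect_lte(abs(mean(y2) - mean(x2)), sum(abs(raw - pmin(pmax(raw, 0), 1))) / length(x2) + 1e-12)
})

test_that("contrast metric matches brute-force decile arithmetic", {
  expect_equal(contrast_metric(gray_image(matrix(0.4, 5, 4))), 0)
  ramp <- gray_image(matrix(seq(0, 0.9, by = 0.1), 2, 5))
  expect_equal(contrast_metric(ramp), 0.9)
  half <- gray_image(matrix(rep(c(0, 1), 10), 4, 5))
  expect_equal(contrast_metric(half), 1)
  expect_error(contrast_metric(gray_image(matrix(0.5, 3, 3))), "10 pixels")
  # brute-force oracle on a random image
  img <- midrange_image(seed = 6, h = 13, w = 7)
  v <- sort(as.vector(rgb_to_hsv(img)$v))
  d <- floor(length(v) / 10)
  expect_equal(contrast_metric(img),
               mean(rev(v)[1:d]) - mean(v[1:d]), tolerance = 1e-12)
})

test_that("contrast metric is strictly increasing in alpha when nothing clips", {
  img <- midrange_image(seed = 7)
  alphas <- c(-0.1, -0.05, 0, 0.05, 0.1)
  metrics <- vapply(alphas, function(a) contrast_metric(adjust_contrast(img, a)), 0)
  expect_true(all(diff(metrics) > 0))
})

test_that("inverse alpha pair restores the original planes", {
  img <- midrange_image(seed = 8)
  a <- 0.1
  back <- adjust_contrast(adjust_contrast(img, a), -a / (1 + a))
  expect_lt(max(abs(back - img)), 1e-6)
})

test_that("contrast report computes deltas and mirrors the intensity argument", {
  img <- generate_scene("diverse", 48, 48, seed = 9)
  same <- contrast_report(img, img)
  expect_equal(same$contrast_delta, 0)
  expect_equal(same$mean_intensity_delta, 0)
  up <- contrast_report(img, adjust_contrast(img, 0.1))
  expect_gt(up$contrast_delta, 0)
  # contrast changes more than mean intensity on color-diverse scenes
  expect_gt(abs(up$contrast_delta), abs(up$mean_intensity_delta))
  expect_error(contrast_report(img, img[1:20, 1:20, , drop = FALSE]), "mismatch")
  luma <- contrast_report(img, adjust_contrast(img, 0.1), intensity = "luma")
  expect_false(identical(luma$contrast_before, up$contrast_before))
})

test_that("clip adjustment reduces to per-frame operation and stays deterministic", {
  img <- midrange_image(seed = 10)
  expect_equal(adjust_clip(list(img), 0.1)[[1]], adjust_contrast(img, 0.1))
  frames <- list(img, img, img)
  out <- adjust_clip(frames, 0.1)
  expect_identical(out[[1]], out[[3]])
  expect_error(adjust_clip(list(), 0.1), "empty")
  zero <- adjust_clip(frames, 0)
  expect_lt(max(abs(zero[[2]] - img)), 1e-6)
  # pooled means differ from per-frame means when frame means differ
  frames2 <- list(img, midrange_image(seed = 11))
  a <- adjust_clip(frames2, 0.1)
  b <- adjust_clip(frames2, 0.1, clip_mean = TRUE)
  expect_gt(max(abs(a[[1]] - b[[1]])), 1e-9)
})

test_that("PNG round trip preserves the image to 8-bit precision", {
  img <- generate_scene("monotone", 32, 24, seed = 12)
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  unlink(path)
})
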