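# Linear contrast control in HSV space, and the contrast / mean-intensity
# change metrics used to characterise its side effects.

#' Convert an RGB image array to HSV planes
#'
#' @param img numeric array H x W x 3 with components in [0, 1].
#' @return list with matrices `h` (in [0, 1), 0 where saturation is 0),
#'   `s` and `v` (in [0, 1]).
#' @export
rgb_to_hsv <- function(img) {
  check_rgb(img)
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]), maxColorValue = 1
  )
  h <- matrix(hsv[1L, ], d[1], d[2])
  s <- matrix(hsv[2L, ], d[1], d[2])
  h[s == 0] <- 0           # hue undefined on the gray axis; pin to 0
  h[h >= 1] <- 0           # wrap convention: hue lives in [0, 1)
  list(h = h, s = s, v = matrix(hsv[3L, ], d[1], d[2]))
}

#' Convert HSV planes back to an RGB image array
#'
#' Standard hexcone inverse; the round trip with [rgb_to_hsv()] is the
#' identity to within 1e-6 per component away from the gray (S = 0) axis.
#'
#' @param hsv list with matrices `h`, `s`, `v` as from [rgb_to_hsv()].
#' @return numeric array H x W x 3 in [0, 1].
#' @export
hsv_to_rgb <- function(hsv) {
  h <- hsv$h; s <- hsv$s; v <- hsv$v
  if (any(h < 0 | h >= 1) || any(s < 0 | s > 1 + 1e-12) ||
      any(v < 0 | v > 1 + 1e-12))
    stopf("HSV components out of range")
  hh <- h * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(dim(as.matrix(h)), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 1)
}

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("expected an H x W x 3 array")
  if (anyNA(img) || any(img < 0) || any(img > 1))
    stopf("RGB components must lie in [0, 1]")
  invisible(img)
}

# X' = X + (X - mean(X)) * alpha on one plane, clipped to [0, 1].
adjust_plane <- function(x, alpha) {
  pmin(pmax(x + (x - mean(x)) * alpha, 0), 1)
}

#' Linear contrast adjustment of an image
#'
#' Converts to HSV and applies the linear operator
#' \eqn{X' = X + (X - X_{avg}) \alpha} independently to the saturation and
#' value planes, where \eqn{X_{avg}} is the plane mean over the whole image.
#' Positive \code{alpha} enhances contrast, negative reduces it; hue is
#' untouched. Planes are clipped to [0, 1] after adjustment.
#'
#' @param img numeric array H x W x 3 in [0, 1].
#' @param alpha finite contrast control parameter.
#' @return adjusted image, same shape as `img`.
#' @export
adjust_contrast <- function(img, alpha) {
  check_rgb(img)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha))
    stopf("alpha must be a single finite number")
  hsv <- rgb_to_hsv(img)
  hsv$s <- adjust_plane(hsv$s, alpha)
  hsv$v <- adjust_plane(hsv$v, alpha)
  hsv_to_rgb(hsv)
}

#' Contrast adjustment of a frame sequence
#'
#' Applies [adjust_contrast()] to each frame. By default the S/V plane means
#' are computed per frame; with \code{clip_mean = TRUE} the means are pooled
#' over the whole clip, which avoids flicker when frame means drift.
#'
#' @param frames nonempty list of H x W x 3 arrays.
#' @param alpha contrast control parameter.
#' @param clip_mean use clip-pooled plane means instead of per-frame means.
#' @return list of adjusted frames, same length and order.
#' @export
adjust_clip <- function(frames, alpha, clip_mean = FALSE) {
  if (!is.list(frames) || length(frames) == 0) stopf("empty frame sequence")
  if (!clip_mean) return(lapply(frames, adjust_contrast, alpha = alpha))
  planes <- lapply(frames, rgb_to_hsv)
  s_avg <- mean(vapply(planes, function(p) mean(p$s), 0))
  v_avg <- mean(vapply(planes, function(p) mean(p$v), 0))
  lapply(planes, function(p) {
    p$s <- pmin(pmax(p$s + (p$s - s_avg) * alpha, 0), 1)
    p$v <- pmin(pmax(p$v + (p$v - v_avg) * alpha, 0), 1)
    hsv_to_rgb(p)
  })
}

# Pixel intensity for the contrast metric: the HSV value plane by default,
# luma as an option.
intensity_plane <- function(img, intensity = c("value", "luma")) {
  intensity <- match.arg(intensity)
  if (intensity == "value") rgb_to_hsv(img)$v
  else 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Decile-spread contrast metric
#'
#' Sorts pixels by intensity and returns the mean intensity of the brightest
#' decile minus that of the darkest decile (decile size
#' \code{max(1, floor(N/10))} pixels). Zero for a constant image, and
#' nonnegative always.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param intensity `"value"` (HSV V plane, default) or `"luma"`.
#' @return nonnegative scalar.
#' @export
contrast_metric <- function(img, intensity = "value") {
  check_rgb(img)
  x <- sort(as.vector(intensity_plane(img, intensity)))
  n <- length(x)
  if (n < 10) stopf("need at least 10 pixels for a decile")
  d <- max(1L, floor(n / 10))
  mean(x[(n - d + 1):n]) - mean(x[1:d])
}

#' Contrast and mean-intensity change report
#'
#' @param original,adjusted images of identical dimensions.
#' @param intensity intensity definition, see [contrast_metric()].
#' @return list with before/after contrast metric and mean intensity and
#'   their deltas (after minus before).
#' @export
contrast_report <- function(original, adjusted, intensity = "value") {
  check_rgb(original); check_rgb(adjusted)
  if (!identical(dim(original), dim(adjusted))) stopf("shape mismatch")
  cb <- contrast_metric(original, intensity)
  ca <- contrast_metric(adjusted, intensity)
  mb <- mean(intensity_plane(original, intensity))
  ma <- mean(intensity_plane(adjusted, intensity))
  list(
    contrast_before = cb, contrast_after = ca, contrast_delta = ca - cb,
    mean_intensity_before = mb, mean_intensity_after = ma,
    mean_intensity_delta = ma - mb
  )
}

#' Read / write an image as PNG
#'
#' 8-bit (or 16-bit) PNG scaled to [0, 1] internally; alpha channels are
#' dropped on read, grayscale is expanded to three planes.
#'
#' @param path file path.
#' @param img H x W x 3 array in [0, 1] (write only).
#' @return `read_image_png` returns an H x W x 3 array.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image_png
#' @export
write_image_png <- function(img, path) {
  check_rgb(img)
  png::writePNG(img, path)
  invisible(path)
}
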