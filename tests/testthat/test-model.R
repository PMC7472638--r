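# The multi-column recognizer: initialization, forward contracts, the
# backpropagation oracle, training behaviour and the evaluation metrics.

tiny_arch <- list(conv = c(2, 2, 3, 3), fc = c(8, 6, 4))

tiny_model <- function(k = 2, seed = 3)
  init_model(k, seed, conv = tiny_arch$conv, fc = tiny_arch$fc)

random_xs <- function(k, n, seed = 1)
  eegcontrast:::with_seed(seed, lapply(seq_len(k), function(j)
    matrix(stats::rnorm(n * 1024), n)))

test_that("initialization is deterministic and column-wise independent", {
  a <- init_model(3, seed = 9)
  b <- init_model(3, seed = 9)
  expect_identical(a$thetas, b$thetas)
  expect_length(a$thetas, 3)
  expect_equal(length(a$thetas[[1]]), length(a$thetas[[2]]))
  expect_false(identical(a$thetas[[1]], a$thetas[[2]]))
  expect_false(identical(init_model(3, seed = 10)$thetas[[1]], a$thetas[[1]]))
  expect_error(init_model(0), "positive")
})

test_that("fused outputs stay strictly inside (-1, 1) on random inputs", {
  m <- tiny_model(k = 2)
  out <- forward(m, random_xs(2, 400, seed = 5))
  expect_equal(dim(out), c(400, 2))
  expect_true(all(abs(out) < 1))
})

test_that("a single-column model returns its column's output and zero input maps to zero", {
  m1 <- tiny_model(k = 1)
  xs <- random_xs(1, 4, seed = 6)
  fused <- forward(m1, xs)
  direct <- eegcontrast:::cpp_mc_forward(m1$thetas, m1$arch$conv, m1$arch$fc, xs)
  expect_equal(unname(fused), direct)
  # biases are zero at init and every stage fixes 0, so zero in -> zero out
  zero <- lapply(1, function(j) matrix(0, 3, 1024))
  expect_equal(max(abs(forward(m1, zero))), 0)
})

test_that("analytic gradients match central finite differences", {
  m <- tiny_model(k = 2, seed = 7)
  xs <- random_xs(2, 3, seed = 8)
  y <- eegcontrast:::with_seed(9, matrix(stats::runif(6, -0.6, 0.6), 3))
  res <- eegcontrast:::cpp_mc_loss_grad(m$thetas, m$arch$conv, m$arch$fc, xs, y)
  eps <- 1e-6
  for (col in 1:2) {
    idx <- eegcontrast:::with_seed(10 + col,
                                   sample(length(m$thetas[[col]]), 60))
    num <- vapply(idx, function(i) {
      tp <- m$thetas; tp[[col]][i] <- tp[[col]][i] + eps
      tm <- m$thetas; tm[[col]][i] <- tm[[col]][i] - eps
      up <- eegcontrast:::cpp_mc_loss_grad(tp, m$arch$conv, m$arch$fc, xs, y)$loss
      dn <- eegcontrast:::cpp_mc_loss_grad(tm, m$arch$conv, m$arch$fc, xs, y)$loss
      (up - dn) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - res$grads[[col]][idx])), 1e-8)
  }
})

test_that("zero-epoch training returns the initial model unchanged", {
  m <- tiny_model()
  set <- list(x = random_xs(2, 8, seed = 11),
              y = matrix(0.1, 8, 2), n = 8, k = 2)
  out <- train(m, set, set, train_config(epochs = 0))
  expect_identical(out$thetas, m$thetas)
  expect_identical(out$norm, m$norm)
})

test_that("training is deterministic and aborts cleanly on bad input", {
  m <- tiny_model()
  set <- list(x = random_xs(2, 32, seed = 12),
              y = eegcontrast:::with_seed(13, matrix(stats::runif(64, -0.5, 0.5), 32)),
              n = 32, k = 2)
  cfgt <- train_config(epochs = 2, batch_size = 8, seed = 4)
  t1 <- train(m, set, set, cfgt)
  t2 <- train(m, set, set, cfgt)
  expect_identical(t1$thetas, t2$thetas)
  expect_identical(t1$history, t2$history)
  bad <- set
  bad$y[1, 1] <- 1.5
  expect_error(train(m, bad, set, cfgt), "inside")
  expect_error(train(m, list(x = NULL, y = set$y), set, cfgt), "empty")
})

test_that("accuracy grows with the separability of synthetic band patterns", {
  # windows carry a channel-pattern whose sign encodes the label; larger
  # amplitude means an easier problem
  make_set <- function(n, amp, seed) {
    lab <- rep(c(-1, 1), length.out = n)
    pattern <- eegcontrast:::with_seed(99, stats::rnorm(1024))
    xs <- eegcontrast:::with_seed(seed, lapply(1:2, function(j)
      t(vapply(seq_len(n), function(i)
        stats::rnorm(1024) + amp * lab[i] * pattern, numeric(1024)))))
    list(x = xs, y = cbind(valence = lab * 0.6, arousal = 0), n = n, k = 2)
  }
  accs <- vapply(c(0.02, 0.1, 0.5), function(amp) {
    tr <- make_set(160, amp, seed = 21)
    te <- make_set(80, amp, seed = 22)
    m <- train(tiny_model(k = 2, seed = 5), tr, te,
               train_config(epochs = 4, batch_size = 16, seed = 6))
    pred <- predict_inputs(m, te)
    mean((pred[, 1] > 0) == (te$y[, 1] > 0))
  }, 0)
  expect_gt(accs[3], 0.9)
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("evaluation metrics match the closed-form confusion formulas", {
  toy <- confusion_metrics(tp = 8, fp = 2, fn = 2, tn = 8)
  expect_equal(unname(toy), c(80, 80, 80))
  perfect <- confusion_metrics(10, 0, 0, 10)
  expect_equal(unname(perfect), c(100, 100, 100))
  inverted <- confusion_metrics(0, 10, 10, 0)
  expect_equal(unname(inverted), c(0, 0, 0))
  # evaluate() binarizes at 0 and reports both dimensions
  m <- tiny_model()
  set <- list(x = random_xs(2, 24, seed = 14),
              y = cbind(valence = rep(c(-0.5, 0.5), 12),
                        arousal = rep(c(0.5, -0.5), 12)), n = 24, k = 2)
  tab <- evaluate(m, set)
  expect_equal(tab$dimension, c("valence", "arousal"))
  expect_true(all(tab$precision >= 0 & tab$precision <= 100))
  single <- set
  single$y[, "valence"] <- 0.5
  expect_warning(evaluate(m, single), "single-class")
})

test_that("trial-level prediction averages the 48 fused input estimates", {
  tr <- stub_processed_trial(seed = 15)
  m <- init_model(5, seed = 16, conv = tiny_arch$conv, fc = tiny_arch$fc)
  est <- predict_trial(m, tr)
  expect_true(all(abs(est) < 1))
  # oracle: segment, forward, average by hand
  seg <- segment_trial(tr, 5)
  xs <- lapply(1:5, function(j)
    t(vapply(1:48, function(i) as.vector(seg$windows[, , j, i]),
             numeric(1024))))
  out <- forward(m, xs)
  expect_equal(unname(est), unname(colMeans(out)), tolerance = 1e-12)
})
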