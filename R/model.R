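# The multi-column emotion recognizer: k structurally identical
# convolutional columns (4 conv + 1 max-pool + 4 FC stages; ReLU hidden
# units, tanh output), each consuming one 32x32 channel-by-time window; the
# fused estimate is the arithmetic mean of the k (valence, arousal) pairs,
# each component strictly inside (-1, 1).

default_arch <- function() list(conv = c(8L, 8L, 16L, 16L), fc = c(64L, 32L, 16L))

#' Initialize a multi-column recognizer
#'
#' Each column's weights are drawn independently with a Xavier-style scaled
#' uniform initializer; biases start at zero, so an all-zero input maps to
#' the estimate (0, 0) at initialization. Deterministic given `seed`.
#'
#' @param k number of columns (default 5).
#' @param seed integer seed.
#' @param conv widths of the four convolution stages.
#' @param fc widths of the three hidden fully connected stages (the fourth
#'   FC stage always has 2 outputs).
#' @return an `mc_model` object.
#' @export
init_model <- function(k = 5, seed = 1, conv = NULL, fc = NULL) {
  if (!is_count(k)) stopf("k must be a positive integer")
  arch <- default_arch()
  if (!is.null(conv)) arch$conv <- as.integer(conv)
  if (!is.null(fc)) arch$fc <- as.integer(fc)
  shapes <- theta_shapes(arch)
  thetas <- with_seed(seed, lapply(seq_len(k), function(j) {
    th <- numeric(sum(vapply(shapes, function(s) s$size, 0L)))
    at <- 0L
    for (s in shapes) {
      if (s$bias) {
        # biases zero
      } else {
        lim <- sqrt(6 / (s$fan_in + s$fan_out))
        th[at + seq_len(s$size)] <- stats::runif(s$size, -lim, lim)
      }
      at <- at + s$size
    }
    th
  }))
  structure(list(k = as.integer(k), arch = arch, thetas = thetas,
                 norm = c(mean = 0, sd = 1), seed = seed),
            class = "mc_model")
}

# Layer shapes in theta order; mirrors the C++ unpacking.
theta_shapes <- function(arch) {
  cv <- arch$conv; fc <- arch$fc
  flat <- 100L * cv[4]
  w <- function(fi, fo) list(size = fi * fo, fan_in = fi, fan_out = fo, bias = FALSE)
  b <- function(fo) list(size = fo, bias = TRUE)
  list(w(9L, cv[1]), b(cv[1]),
       w(9L * cv[1], cv[2]), b(cv[2]),
       w(9L * cv[2], cv[3]), b(cv[3]),
       w(9L * cv[3], cv[4]), b(cv[4]),
       w(flat, fc[1]), b(fc[1]),
       w(fc[1], fc[2]), b(fc[2]),
       w(fc[2], fc[3]), b(fc[3]),
       w(fc[3], 2L), b(2L))
}

normalize_xs <- function(model, xs) {
  lapply(xs, function(m) (m - model$norm[["mean"]]) / model$norm[["sd"]])
}

#' Forward pass: fused (valence, arousal) estimates
#'
#' Column `j` consumes window `j`; the fused estimate is the mean of the k
#' column outputs, so both components lie strictly inside (-1, 1).
#'
#' @param model an `mc_model`.
#' @param xs list of k matrices (n x 1024), one per column, or a single
#'   32 x 32 x k array for one input.
#' @return n x 2 matrix with columns valence, arousal.
#' @export
forward <- function(model, xs) {
  if (is.array(xs) && length(dim(xs)) == 3) {
    k <- dim(xs)[3]
    xs <- lapply(seq_len(k), function(j) matrix(as.vector(xs[, , j]), 1))
  }
  if (length(xs) != model$k) stopf("window count does not match model k")
  out <- cpp_mc_forward(model$thetas, model$arch$conv, model$arch$fc,
                        normalize_xs(model, xs))
  colnames(out) <- c("valence", "arousal")
  out
}

#' Train the recognizer
#'
#' Minimizes the mean-squared error between fused outputs and (valence,
#' arousal) targets with Adam, mini-batched, early-stopped on validation
#' loss, returning the best-validation checkpoint. Inputs are standardized
#' with the training set's global mean and standard deviation (stored in the
#' model and applied in every forward pass). Deterministic given
#' `config$seed` under single-threaded execution.
#'
#' @param model an `mc_model` from [init_model()].
#' @param train_set,val_set input sets as built by [make_dataset()] (fields
#'   `x`, list of k matrices, and `y`, n x 2 targets).
#' @param config list of training settings; see [train_config()].
#' @return the trained model with a `history` data.frame attached
#'   (`$history`: epoch, train_loss, val_loss).
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  if (is.null(train_set$x) || nrow(train_set$y) == 0) stopf("empty training set")
  if (any(abs(train_set$y) >= 1)) stopf("targets must lie strictly inside (-1, 1)")
  if (config$epochs == 0) return(model)
  n <- nrow(train_set$y)
  mu <- mean(vapply(train_set$x, mean, 0))
  sdv <- sqrt(mean(vapply(train_set$x, function(m) mean((m - mu)^2), 0)))
  if (sdv == 0) sdv <- 1
  model$norm <- c(mean = mu, sd = sdv)
  xs <- normalize_xs(model, train_set$x)
  adam <- lapply(model$thetas, function(th)
    list(m = numeric(length(th)), v = numeric(length(th))))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
  best <- list(loss = Inf, thetas = model$thetas)
  hist <- data.frame(epoch = integer(), train_loss = double(),
                     val_loss = double())
  patience_left <- config$patience
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 7L, ep), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bi in batches) {
      xb <- lapply(xs, function(m) m[bi, , drop = FALSE])
      res <- cpp_mc_loss_grad(model$thetas, model$arch$conv, model$arch$fc,
                              xb, train_set$y[bi, , drop = FALSE])
      if (!is.finite(res$loss)) stopf("non-finite loss at epoch %d", ep)
      tr_loss <- tr_loss + res$loss * length(bi)
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (j in seq_len(model$k)) {
        g <- res$grads[[j]]
        adam[[j]]$m <- b1 * adam[[j]]$m + (1 - b1) * g
        adam[[j]]$v <- b2 * adam[[j]]$v + (1 - b2) * g^2
        model$thetas[[j]] <- model$thetas[[j]] -
          config$lr * corr * adam[[j]]$m / (sqrt(adam[[j]]$v) + eps)
      }
    }
    tr_loss <- tr_loss / n
    vl <- if (!is.null(val_set) && nrow(val_set$y) > 0)
      eval_loss(model, val_set) else tr_loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, thetas = model$thetas)
      patience_left <- config$patience
    } else {
      patience_left <- patience_left - 1
      if (patience_left <= 0) break
    }
  }
  model$thetas <- best$thetas
  model$history <- hist
  model
}

#' Training configuration
#'
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed seed for batch shuffling.
#' @return a list of validated settings.
#' @export
train_config <- function(epochs = 50, batch_size = 64, lr = 1e-3,
                         patience = 5, seed = 1) {
  if (epochs < 0 || !is.finite(lr) || !is_count(batch_size))
    stopf("invalid training configuration")
  list(epochs = epochs, batch_size = batch_size, lr = lr,
       patience = patience, seed = seed,
       optimizer = "adam", loss = "mse")
}

# Mean fused prediction loss over an input set, batched.
eval_loss <- function(model, set, batch = 512L) {
  n <- nrow(set$y)
  tot <- 0
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(n, at + batch - 1L)
    out <- forward(model, lapply(set$x, function(m) m[idx, , drop = FALSE]))
    tot <- tot + sum((out - set$y[idx, , drop = FALSE])^2)
  }
  tot / (n * 2)
}

#' Batched fused predictions over an input set
#'
#' @param model an `mc_model`.
#' @param set an input set from [make_dataset()].
#' @param batch batch size for the forward passes.
#' @return n x 2 matrix of (valence, arousal) estimates.
#' @export
predict_inputs <- function(model, set, batch = 512L) {
  n <- nrow(set$y)
  out <- matrix(0, n, 2, dimnames = list(NULL, c("valence", "arousal")))
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(n, at + batch - 1L)
    out[idx, ] <- forward(model, lapply(set$x, function(m) m[idx, , drop = FALSE]))
  }
  out
}

#' Classification metrics at the rating midpoint
#'
#' Binarizes targets and fused predictions at 0 (the (-1, 1) image of
#' rating 5, ties low) and reports precision, recall and F1 per dimension,
#' in percent. A degenerate single-class test set yields 0 for the
#' undefined ratios, with a warning.
#'
#' @param model an `mc_model`.
#' @param test_set labeled input set.
#' @return data.frame with one row per dimension.
#' @export
evaluate <- function(model, test_set) {
  pred <- predict_inputs(model, test_set)
  res <- lapply(1:2, function(d) {
    truth <- test_set$y[, d] > 0
    hat <- pred[, d] > 0
    if (length(unique(truth)) < 2)
      warning("single-class test set: some metrics undefined, reported as 0")
    tp <- sum(hat & truth); fp <- sum(hat & !truth); fn <- sum(!hat & truth)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(dimension = c("valence", "arousal")[d],
               precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
               accuracy = 100 * mean(hat == truth))
  })
  do.call(rbind, res)
}

#' Classification metrics from a confusion count
#'
#' Precision, recall and F1 (in percent) from true/false positive and
#' negative counts; the closed-form definitions used by [evaluate()].
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return named numeric vector (precision, recall, f1), percent.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1)
}

#' Trial-level (valence, arousal) estimate
#'
#' Segments a processed trial with the model's column count and averages
#' the fused estimates of all its inputs (48 for k = 5).
#'
#' @param model an `mc_model`.
#' @param trial a `processed_trial`.
#' @return named numeric vector c(valence, arousal).
#' @export
predict_trial <- function(model, trial) {
  seg <- segment_trial(trial, model$k)
  n <- dim(seg$windows)[4]
  xs <- lapply(seq_len(model$k), function(j)
    t(vapply(seq_len(n), function(i) as.vector(seg$windows[, , j, i]),
             numeric(1024))))
  out <- forward(model, xs)
  c(valence = mean(out[, 1]), arousal = mean(out[, 2]))
}
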