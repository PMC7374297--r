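test_that("weighted BCE matches its defining formula", {
  # perfect confident predictions drive the loss to zero
  y <- matrix(c(1L, 0L), 2, 1)
  p <- matrix(c(1 - 1e-9, 1e-9), 2, 1)
  expect_lt(weighted_bce_loss(p, y, beta = 2), 1e-6)
  # single frame, y = 1, p = 0.5, beta = 2 -> 2 log 2
  expect_equal(weighted_bce_loss(matrix(0.5), matrix(1L), beta = 2),
               2 * log(2), tolerance = 1e-12)
  # random batch against the scalar double-loop transcription
  set.seed(40)
  p <- matrix(runif(10 * 7), 10, 7)
  y <- matrix(rbinom(70, 1, 0.3), 10, 7)
  expect_equal(weighted_bce_loss(p, y, beta = 2), oracle_wbce(p, y, 2),
               tolerance = 1e-10)
  # beta = 1 reduces to plain binary cross-entropy (independent expression)
  plain <- -sum(y * log(p) + (1 - y) * log(1 - p)) / ncol(p)
  expect_equal(weighted_bce_loss(p, y, beta = 1), plain, tolerance = 1e-10)
  # clamping keeps the loss finite at exact 0/1 probabilities
  expect_true(is.finite(weighted_bce_loss(matrix(c(0, 1)), matrix(c(1L, 0L)), 2)))
  # invariant to batch order
  ord <- sample(7)
  expect_equal(weighted_bce_loss(p[, ord], y[, ord], 2),
               weighted_bce_loss(p, y, 2), tolerance = 1e-12)
})

test_that("one small full-batch gradient step decreases the loss", {
  oq <- asNamespace("octqrs")
  net <- toy_net(alpha = 0.25, seed = 41)
  set.seed(41)
  x <- array(rnorm(2 * 40 * 8), c(2, 40, 8))
  y <- matrix(rbinom(80, 1, 0.25), 10, 8)
  fwd <- oq$network_forward(net, x, train = TRUE)
  lg <- oq$loss_and_grad(fwd$logits, y, 2)
  bwd <- oq$network_backward(net, fwd, lg$dlogits)
  lr <- 1e-3
  sgd <- function(p, g) {
    if (is.list(g)) {
      nm <- names(g)
      for (i in seq_along(g)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
        if (!is.null(g[[i]])) p[[key]] <- sgd(p[[key]], g[[i]])
      }
      p
    } else p - lr * g
  }
  net2 <- net
  upd <- sgd(net[c("blocks", "gru", "cls")], bwd$grads)
  for (nm in names(upd)) net2[[nm]] <- upd[[nm]]
  fwd2 <- oq$network_forward(net2, x, train = TRUE)
  l2 <- oq$loss_and_grad(fwd2$logits, y, 2)$loss
  expect_lt(l2, lg$loss)
})

test_that("training on easy separable windows reduces the loss and is seeded", {
  # easy toy task: positive frames carry a large synthetic spike
  set.seed(42)
  n <- 64L
  x <- array(rnorm(2 * 40 * n, sd = 0.1), c(2, 40, n))
  y <- matrix(0L, 10, n)
  for (i in seq_len(n)) {
    pos <- sample(0:9, 3)
    y[pos + 1, i] <- 1L
    for (f in pos) x[, f * 4 + 2, i] <- x[, f * 4 + 2, i] + 3
  }
  w <- octqrs:::new_windows(x, y, tibble::tibble(record_id = "toy",
                                                 start = seq_len(n)))
  cfg <- network_config(in_channels = 2L, window_length = 40L,
                        frames_per_window = 10L, block_filters = c(4L, 6L, 6L),
                        alpha = 0.25, gru_hidden = 4L, dropout_rate = 0.4,
                        normalize = FALSE)
  fit1 <- train(build_network(cfg, seed = 7), w, w,
                train_config(epochs = 3, batch_size = 16, seed = 7))
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  fit2 <- train(build_network(cfg, seed = 7), w, w,
                train_config(epochs = 3, batch_size = 16, seed = 7))
  expect_identical(fit1$net, fit2$net)
  expect_equal(fit1$history, fit2$history)
  # empty data errors
  w0 <- octqrs:::new_windows(x[, , 0, drop = FALSE], y[, 0, drop = FALSE],
                             w$meta[0, ])
  expect_error(train(build_network(cfg, seed = 7), w0, w,
                     train_config(epochs = 1)), "non-empty")
})

test_that("metrics follow the precision/recall/F1 definitions", {
  m <- metrics_from_counts(tp = 2, fp = 1, fn = 0)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 0.8)
  expect_false(m$degenerate)
  # all-negative predictor on a set with positives
  m0 <- metrics_from_counts(tp = 0, fp = 0, fn = 10)
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)
  expect_true(m0$degenerate)
  # F1 bounds as a property over random counts
  set.seed(43)
  for (i in 1:30) {
    m <- metrics_from_counts(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    expect_lte(m$f1, min(2 * m$precision, 2 * m$recall) + 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("evaluate counts frames through the real prediction path", {
  net <- toy_net(alpha = 0, seed = 44)
  set.seed(44)
  x <- array(rnorm(2 * 40 * 5), c(2, 40, 5))
  y <- matrix(rbinom(50, 1, 0.3), 10, 5)
  w <- octqrs:::new_windows(x, y, tibble::tibble(record_id = "t", start = 1:5))
  m <- evaluate(net, w)
  pred <- predict(net, w, type = "class")
  expect_equal(m$tp, sum(pred == 1 & y == 1))
  expect_equal(m$fp, sum(pred == 1 & y == 0))
  expect_equal(m$fn, sum(pred == 0 & y == 1))
  expect_equal(m$tp + m$fp + m$fn + sum(pred == 0 & y == 0), 50)
})
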