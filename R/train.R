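#' Training configuration
#'
#' The optimization recipe of the detector: Adam (learning rate 1e-3,
#' beta1 0.9, beta2 0.999, epsilon 1e-8), weighted binary cross-entropy
#' with positive-class weight `loss_beta = 2` to offset the scarcity of
#' fetal-QRS frames, Glorot initialization, dropout 0.4, batch size 64,
#' and model selection by validation F1.
#'
#' @param epochs Training epochs.
#' @param batch_size Windows per batch.
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param loss_beta Positive-class weight of the loss (> 0).
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @return A list of class `octqrs_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, loss_beta = 2, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, loss_beta > 0, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, loss_beta = loss_beta,
                 seed = as.integer(seed)),
            class = "octqrs_train_config")
}

#' Weighted binary cross-entropy over frame predictions
#'
#' `mean over windows of sum over frames of
#' -[beta * y * log(p) + (1 - y) * log(1 - p)]`, where `p` is the
#' positive-class probability. `beta > 1` up-weights the cost of missing a
#' positive frame; `beta = 1` recovers plain binary cross-entropy.
#' Probabilities are clamped to `[eps, 1 - eps]` so the loss is never
#' non-finite.
#'
#' @param probs Positive-class probabilities: vector, `[frames x n]`
#'   matrix, or `[frames x classes x n]` probability array (positive class
#'   in column 2).
#' @param labels 0/1 labels with the same frame layout.
#' @param beta Positive-class weight.
#' @param eps Clamping constant.
#' @return A single non-negative number.
#' @export
weighted_bce_loss <- function(probs, labels, beta = 2, eps = 1e-7) {
  stopifnot(beta > 0)
  if (is.array(probs) && length(dim(probs)) == 3L) probs <- probs[, 2, ]
  p <- pmin(pmax(as.numeric(probs), eps), 1 - eps)
  y <- as.numeric(labels)
  stopifnot(length(p) == length(y))
  n_windows <- if (is.matrix(probs)) ncol(probs) else 1L
  -sum(beta * y * log(p) + (1 - y) * log(1 - p)) / n_windows
}

# Loss and gradient w.r.t. logits for a (classes, frames, B) logit array.
loss_and_grad <- function(logits, y, beta, eps = 1e-7) {
  d <- dim(logits)
  probs <- softmax_frames(logits)
  p1 <- pmin(pmax(matrix(probs[2, , ], d[2], d[3]), eps), 1 - eps)
  loss <- -sum(beta * y * log(p1) + (1 - y) * log(1 - p1)) / d[3]
  # d loss / d logits through the two-class softmax
  dl1 <- (-beta * y * (1 - p1) + (1 - y) * p1) / d[3]
  dlogits <- array(0, d)
  dlogits[2, , ] <- dl1
  dlogits[1, , ] <- -dl1
  list(loss = loss, dlogits = dlogits, p1 = p1)
}

adam_update <- function(params, grads, state, cfg, t) {
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  rec <- function(p, g, m, v) {
    if (is.list(g)) {
      nm <- names(g)
      for (i in seq_along(g)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
        if (is.null(g[[i]])) next
        r <- rec(p[[key]], g[[i]], m[[key]], v[[key]])
        p[[key]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      if (is.null(m)) m <- g * 0
      if (is.null(v)) v <- g * 0
      m <- cfg$beta1 * m + (1 - cfg$beta1) * g
      v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
      list(p = p - lr_t * m / (sqrt(v) + cfg$epsilon), m = m, v = v)
    }
  }
  if (is.null(state$m)) {
    zero_like <- function(g) if (is.list(g)) lapply(g, zero_like) else
      if (is.null(g)) NULL else g * 0
    state$m <- zero_like(grads); state$v <- zero_like(grads)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

apply_param_tree <- function(net, params) {
  for (nm in names(params)) net[[nm]] <- params[[nm]]
  net
}

#' Train the detector
#'
#' Runs Adam on the weighted binary cross-entropy for `config$epochs`
#' epochs, evaluating frame-level F1 on the validation windows after every
#' epoch, and returns the weights of the best validation epoch together
#' with the full history. Fully deterministic for a fixed seed (data order,
#' initialization, dropout).
#'
#' @param net An [build_network()] model (its weights are the starting
#'   point; rebuild with a seed for a fresh deterministic start).
#' @param train_windows,val_windows [extract_windows()] objects with labels.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss and validation F1.
#' @return An object of class `octqrs_fit`: list with `net` (best-epoch
#'   model), `history` (per-epoch tibble), `best_epoch`, `config`.
#' @export
train <- function(net, train_windows, val_windows,
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "octqrs_network"),
            inherits(train_windows, "octqrs_windows"),
            inherits(val_windows, "octqrs_windows"))
  n <- dim(train_windows$x)[3]
  if (n == 0L || dim(val_windows$x)[3] == 0L)
    abort("training and validation window sets must be non-empty")
  set.seed(config$seed)
  cfg <- net$config
  x_all <- train_windows$x
  if (cfg$normalize) x_all <- standardize_windows(x_all)
  y_all <- train_windows$y
  state <- list()
  history <- vector("list", config$epochs)
  best <- list(f1 = -Inf, net = net, epoch = 0L)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (bi in batches) {
      xb <- x_all[, , bi, drop = FALSE]
      yb <- y_all[, bi, drop = FALSE]
      fwd <- network_forward(net, xb, train = TRUE)
      net <- fwd$net  # batch-norm running statistics advance
      lg <- loss_and_grad(fwd$logits, yb, config$loss_beta)
      if (!is.finite(lg$loss))
        abort(sprintf("non-finite loss at epoch %d; aborting training", epoch))
      bwd <- network_backward(net, fwd, lg$dlogits)
      step <- step + 1L
      upd <- adam_update(net[c("blocks", "gru", "cls")], bwd$grads, state,
                         config, step)
      net <- apply_param_tree(net, upd$params)
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(bi)
    }
    val <- evaluate(net, val_windows)
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = epoch_loss / n,
                               val_precision = val$precision,
                               val_recall = val$recall,
                               val_f1 = val$f1)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val F1 %.3f",
                      epoch, epoch_loss / n, val$f1))
    if (val$f1 > best$f1) best <- list(f1 = val$f1, net = net, epoch = epoch)
  }
  structure(list(net = best$net, final_net = net,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, config = config),
            class = "octqrs_fit")
}

#' @export
print.octqrs_fit <- function(x, ...) {
  cat(sprintf("<octqrs_fit: %d epochs, best validation F1 %.3f at epoch %d>\n",
              nrow(x$history), max(x$history$val_f1), x$best_epoch))
  invisible(x)
}

#' @export
tidy.octqrs_fit <- function(x, ...) x$history

#' @export
glance.octqrs_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_f1 = max(x$history$val_f1),
         final_train_loss = x$history$train_loss[nrow(x$history)],
         alpha = x$net$config$alpha, n_params = n_params(x$net))
}

#' Frame-level precision, recall and F1 of a detector
#'
#' Each 100-ms frame is one classification unit: the predicted class is the
#' argmax of the frame's probability pair, and true positives, false
#' positives and false negatives are accumulated over all frames of all
#' windows. Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1
#' their harmonic mean; a zero denominator yields 0 with the `degenerate`
#' flag set.
#'
#' @param model An `octqrs_network` or `octqrs_fit` (its best model is
#'   used).
#' @param windows Labeled [extract_windows()] object.
#' @return A one-row tibble of class `octqrs_metrics` with columns `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`, `degenerate`.
#' @export
evaluate <- function(model, windows) {
  if (inherits(model, "octqrs_fit")) model <- model$net
  stopifnot(inherits(model, "octqrs_network"),
            inherits(windows, "octqrs_windows"))
  pred <- predict(model, windows, type = "class")
  metrics_from_counts(
    tp = sum(pred == 1L & windows$y == 1L),
    fp = sum(pred == 1L & windows$y == 0L),
    fn = sum(pred == 0L & windows$y == 1L))
}

#' @rdname evaluate
#' @param tp,fp,fn Frame counts.
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                   recall = recall, f1 = f1,
                   degenerate = (tp + fp == 0) || (tp + fn == 0)),
            class = c("octqrs_metrics", class(tibble())))
}
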