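# Whole-network forward and backward passes.
#
# The trunk works on frequency-factorized maps held as plain lists
# (high/low 3-d arrays), the head on pooled frame sequences.  Training-mode
# forward passes record every intermediate needed by the manual backward
# pass; inference uses batch-norm running statistics and no dropout.

bn_branch_forward <- function(x, bn, eps, momentum, train) {
  if (is.null(x)) return(list(y = NULL, cache = NULL, bn = bn))
  if (train) {
    st <- channel_stats_cpp(x)
    mu <- as.numeric(st$mu)
    v <- as.numeric(st$var)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  r <- bn_fwd_cpp(x, mu, inv_sd, bn$gamma, bn$beta)
  list(y = r$y,
       cache = if (train) list(xhat = r$xhat, inv_sd = inv_sd, gamma = bn$gamma),
       bn = bn)
}

bn_branch_backward <- function(dy, cache) {
  r <- bn_bwd_cpp(dy, cache$xhat, cache$gamma, cache$inv_sd)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

bn_fm_forward <- function(fm, bn, eps, momentum, train) {
  h <- bn_branch_forward(fm$high, bn$high, eps, momentum, train)
  l <- bn_branch_forward(fm$low, bn$low, eps, momentum, train)
  list(fm = freq_map(h$y, l$y, fm$alpha),
       cache = list(high = h$cache, low = l$cache),
       bn = list(high = h$bn, low = l$bn))
}

bn_fm_backward <- function(dfm, cache) {
  gh <- gl <- NULL
  dh <- dl <- NULL
  if (!is.null(dfm$high)) {
    r <- bn_branch_backward(dfm$high, cache$high)
    dh <- r$dx; gh <- list(gamma = r$dgamma, beta = r$dbeta)
  }
  if (!is.null(dfm$low)) {
    r <- bn_branch_backward(dfm$low, cache$low)
    dl <- r$dx; gl <- list(gamma = r$dgamma, beta = r$dbeta)
  }
  list(dfm = list(high = dh, low = dl), grads = list(high = gh, low = gl))
}

relu_fm <- function(fm) {
  f <- function(x) if (is.null(x)) NULL else relu_cpp(x)
  freq_map(f(fm$high), f(fm$low), fm$alpha)
}

relu_fm_backward <- function(dfm, fm_out) {
  f <- function(dx, y) if (is.null(dx)) NULL else relu_bwd_cpp(dx, y)
  list(high = f(dfm$high, fm_out$high), low = f(dfm$low, fm_out$low))
}

add_fm <- function(a, b) {
  f <- function(x, y) if (is.null(x)) y else if (is.null(y)) x else add_cubes_cpp(x, y)
  freq_map(f(a$high, b$high), f(a$low, b$low), a$alpha)
}

# Backward pass of octconv_forward given the cached input map.
octconv_backward <- function(x_fm, layer, dy) {
  si <- split_channels(layer$in_channels, layer$alpha_in)
  g <- list(W_hh = array(0, dim(layer$W_hh)), W_hl = array(0, dim(layer$W_hl)),
            W_lh = array(0, dim(layer$W_lh)), W_ll = array(0, dim(layer$W_ll)),
            b_h = numeric(length(layer$b_h)), b_l = numeric(length(layer$b_l)))
  dx_h <- dx_l <- NULL
  k <- layer$kernel_length
  pl <- pad_left_for(k)
  if (!is.null(dy$high)) {
    g$b_h <- rowSums(dy$high, dims = 1L)
    if (si[1] > 0) {
      r <- conv1d_bwd_cpp(as_fmap3(x_fm$high), layer$W_hh, dy$high, pl)
      dx_h <- r$dx; g$W_hh <- r$dw
    }
    if (si[2] > 0) {
      dlow_out <- half_sum(dy$high)  # upsample backward: sum consecutive pairs
      r <- conv1d_bwd_cpp(as_fmap3(x_fm$low), layer$W_lh, dlow_out, pl)
      dx_l <- r$dx; g$W_lh <- r$dw
    }
  }
  if (!is.null(dy$low)) {
    g$b_l <- rowSums(dy$low, dims = 1L)
    if (si[2] > 0) {
      r <- conv1d_bwd_cpp(as_fmap3(x_fm$low), layer$W_ll, dy$low, pl)
      dx_l <- if (is.null(dx_l)) r$dx else dx_l + r$dx
      g$W_ll <- r$dw
    }
    if (si[1] > 0) {
      pooled <- average_pool_halve(as_fmap3(x_fm$high))
      r <- conv1d_bwd_cpp(pooled, layer$W_hl, dy$low, pl)
      g$W_hl <- r$dw
      dpool <- upsample_double(r$dx) / 2  # pooling backward: spread the mean
      dx_h <- if (is.null(dx_h)) dpool else dx_h + dpool
    }
  }
  list(dx = list(high = dx_h, low = dx_l), grads = g)
}

half_sum <- function(x) half_sum_cpp(x)

trunk_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  fm <- freq_map(as_fmap3(x), NULL, 0)
  caches <- list()
  for (b in seq_along(net$blocks)) {
    blk <- net$blocks[[b]]
    block_in <- fm
    ccache <- list()
    nconv <- length(blk$convs)
    for (j in seq_len(nconv)) {
      cv <- blk$convs[[j]]
      conv_in <- fm
      pre <- octconv_forward(fm, cv$layer)
      bnr <- bn_fm_forward(pre, cv$bn, cfg$bn_eps, cfg$bn_momentum, train)
      net$blocks[[b]]$convs[[j]]$bn <- bnr$bn
      if (j < nconv) {
        out <- relu_fm(bnr$fm)
        ccache[[j]] <- list(conv_in = conv_in, bn_cache = bnr$cache, act = out)
        fm <- out
      } else {
        sc <- octconv_forward(block_in, blk$shortcut)
        merged <- add_fm(bnr$fm, sc)
        out <- relu_fm(merged)
        ccache[[j]] <- list(conv_in = conv_in, bn_cache = bnr$cache, act = out)
        fm <- out
      }
    }
    caches[[b]] <- list(block_in = block_in, convs = ccache)
  }
  list(out = fm$high, fm = fm, caches = if (train) caches, net = net)
}

trunk_backward <- function(net, caches, dA) {
  dfm <- list(high = dA, low = NULL)
  gblocks <- vector("list", length(net$blocks))
  for (b in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[b]]
    cache <- caches[[b]]
    nconv <- length(blk$convs)
    gconvs <- vector("list", nconv)
    dsc_in <- NULL
    for (j in rev(seq_len(nconv))) {
      cc <- cache$convs[[j]]
      dfm <- relu_fm_backward(dfm, cc$act)
      if (j == nconv) {
        # gradient splits between the BN path and the shortcut path
        sc_b <- octconv_backward(cache$block_in, blk$shortcut, dfm)
        gsc <- sc_b$grads
        dsc_in <- sc_b$dx
      }
      bnb <- bn_fm_backward(dfm, cc$bn_cache)
      cvb <- octconv_backward(cc$conv_in, blk$convs[[j]]$layer, bnb$dfm)
      gconvs[[j]] <- list(layer = cvb$grads, bn = bnb$grads)
      dfm <- cvb$dx
    }
    dfm <- list(
      high = if (is.null(dfm$high)) dsc_in$high
             else if (is.null(dsc_in$high)) dfm$high else dfm$high + dsc_in$high,
      low = if (is.null(dfm$low)) dsc_in$low
            else if (is.null(dsc_in$low)) dfm$low else dfm$low + dsc_in$low)
    gblocks[[b]] <- list(convs = gconvs, shortcut = gsc)
  }
  list(grads = gblocks, dx = dfm$high)
}

head_forward <- function(net, A, train = FALSE, dropout_masks = NULL,
                         keep_cache = train) {
  cfg <- net$config
  A <- as_fmap3(A)
  pooled <- segment_pool(A, cfg$frames_per_window)
  d <- dim(pooled)
  masks <- list()
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    m1 <- if (is.null(dropout_masks)) {
      array((runif(prod(d)) < keep) / keep, d)
    } else dropout_masks$m1
    pooled_d <- pooled * m1
    masks$m1 <- m1
  } else pooled_d <- pooled
  f <- gru_seq_forward(pooled_d, net$gru$fwd, keep_cache = keep_cache)
  xb <- pooled_d[, rev(seq_len(d[2])), , drop = FALSE]
  bwd <- gru_seq_forward(xb, net$gru$bwd, keep_cache = keep_cache)
  hb <- bwd$out[, rev(seq_len(d[2])), , drop = FALSE]
  H <- array(0, c(2L * cfg$gru_hidden, d[2], d[3]))
  H[seq_len(cfg$gru_hidden), , ] <- f$out
  H[cfg$gru_hidden + seq_len(cfg$gru_hidden), , ] <- hb
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    m2 <- if (is.null(dropout_masks)) {
      array((runif(length(H)) < keep) / keep, dim(H))
    } else dropout_masks$m2
    H_d <- H * m2
    masks$m2 <- m2
  } else H_d <- H
  logits <- array(net$cls$W %*% matrix(H_d, dim(H_d)[1]) + net$cls$b,
                  c(cfg$num_classes, d[2], d[3]))
  cache <- list(pooled = pooled, pooled_d = pooled_d, gru_f = f$cache,
                gru_b = bwd$cache, H_d = H_d, masks = masks,
                time_length = dim(A)[2])
  list(logits = logits, cache = cache)
}

head_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  d <- dim(dlogits)  # (classes, frames, B)
  dl <- matrix(dlogits, d[1])
  Hd <- matrix(cache$H_d, dim(cache$H_d)[1])
  gW <- dl %*% t(Hd)
  gb <- rowSums(dl)
  dH <- array(t(net$cls$W) %*% dl, dim(cache$H_d))
  if (!is.null(cache$masks$m2)) dH <- dH * cache$masks$m2
  h <- cfg$gru_hidden
  dHf <- dH[seq_len(h), , , drop = FALSE]
  dHb <- dH[h + seq_len(h), , , drop = FALSE]
  gf <- gru_seq_backward(net$gru$fwd, cache$gru_f, dHf)
  gbk <- gru_seq_backward(net$gru$bwd, cache$gru_b,
                          dHb[, rev(seq_len(d[2])), , drop = FALSE])
  dpooled <- gf$dx + gbk$dx[, rev(seq_len(d[2])), , drop = FALSE]
  if (!is.null(cache$masks$m1)) dpooled <- dpooled * cache$masks$m1
  dA <- segment_pool_backward(dpooled, cache$time_length)
  list(grads = list(gru = list(fwd = gf$grads, bwd = gbk$grads),
                    cls = list(W = gW, b = gb)),
       dA = dA)
}

network_forward <- function(net, x, train = FALSE) {
  tr <- trunk_forward(net, x, train = train)
  hd <- head_forward(tr$net, tr$out, train = train)
  list(logits = hd$logits, trunk_out = tr$out,
       trunk_cache = tr$caches, head_cache = hd$cache, net = tr$net)
}

network_backward <- function(net, fwd, dlogits) {
  hb <- head_backward(net, fwd$head_cache, dlogits)
  tb <- trunk_backward(net, fwd$trunk_cache, hb$dA)
  list(grads = list(blocks = tb$grads, gru = hb$grads$gru, cls = hb$grads$cls),
       dA = hb$dA)
}

softmax_frames <- function(logits) {
  d <- dim(logits)
  m <- apply(logits, c(2, 3), max)
  e <- exp(logits - array(rep(m, each = d[1]), d))
  s <- apply(e, c(2, 3), sum)
  e / array(rep(s, each = d[1]), d)
}

#' Run the detector on signal windows
#'
#' Maps each 4 x 1000 window through the trunk, per-frame pooling,
#' bidirectional GRU and shared softmax, yielding a probability pair per
#' 100-ms frame. Inference is deterministic: dropout is disabled and batch
#' normalization uses running statistics.
#'
#' @param object An `octqrs_network`.
#' @param windows A `[channels x window_length]` matrix, a
#'   `[channels x window_length x n]` array, or an object from
#'   [extract_windows()].
#' @param type `"prob"` for class probabilities, `"class"` for 0/1 frame
#'   decisions (argmax).
#' @param ... Unused.
#' @return For a single window, a `[frames x classes]` matrix of
#'   probabilities (rows sum to 1) or a length-`frames` 0/1 vector; for a
#'   batch, an array/matrix with a trailing window dimension.
#' @export
predict.octqrs_network <- function(object, windows, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- windows_to_array(windows, object$config)
  single <- is.matrix(windows) ||
    (is.array(windows) && length(dim(windows)) == 2L)
  if (object$config$normalize) x <- standardize_windows(x)
  # bound peak memory: run the trunk on at most 64 windows at a time
  nb <- dim(x)[3]
  chunks <- split(seq_len(nb), ceiling(seq_len(nb) / 64))
  probs <- array(0, c(object$config$num_classes,
                      object$config$frames_per_window, nb))
  for (ci in chunks) {
    out <- network_forward(object, x[, , ci, drop = FALSE], train = FALSE)
    probs[, , ci] <- softmax_frames(out$logits)
  }
  if (type == "prob") {
    res <- aperm(probs, c(2, 1, 3))    # (frames, classes, B)
    if (single) res[, , 1] else res
  } else {
    cls <- apply(probs, c(2, 3), which.max) - 1L  # (frames, B)
    if (single) cls[, 1] else cls
  }
}

windows_to_array <- function(windows, cfg) {
  if (inherits(windows, "octqrs_windows")) return(windows$x)
  x <- if (is.matrix(windows)) array(windows, c(dim(windows), 1L)) else windows
  if (!is.array(x) || length(dim(x)) != 3L)
    abort("windows must be a [channels x time] matrix, a [channels x time x n] array, or an octqrs_windows object")
  if (dim(x)[1] != cfg$in_channels || dim(x)[2] != cfg$window_length)
    abort(sprintf("expected windows of %d x %d, got %d x %d",
                  cfg$in_channels, cfg$window_length, dim(x)[1], dim(x)[2]))
  x
}

# Per-window, per-channel standardization (zero mean, unit variance).
standardize_windows <- function(x, eps = 1e-6) {
  d <- dim(x)
  m <- apply(x, c(1, 3), mean)                        # (channels, windows)
  s2 <- apply(x, c(1, 3), function(v) mean(v * v)) - m^2
  s <- sqrt(pmax(s2, 0)) + eps
  for (b in seq_len(d[3])) {
    x[, , b] <- (x[, , b] - m[, b]) / s[, b]
  }
  x
}
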