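#' Detector configuration
#'
#' Describes the fetal-QRS detector: a residual convolutional trunk of three
#' blocks (three octave convolutions each, kernel lengths 8/5/3 within every
#' block, 64/128/128 filters per block, batch normalization then ReLU after
#' each convolution, a 1x1 convolution shortcut bridging every block), a
#' per-frame global average pooling stage splitting the 1-second window into
#' ten 100-ms frames, a bidirectional GRU (hidden size 32) over the ten
#' pooled vectors, and a shared two-class softmax applied at every frame.
#'
#' @param in_channels Number of abdominal ECG channels (4).
#' @param window_length Samples per window (1000 = 1 s at 1000 Hz).
#' @param frames_per_window Decision frames per window (10, i.e. 100 ms each).
#' @param block_filters Output channels of the three residual blocks.
#' @param block_kernel_lengths Kernel lengths of the three convolutions
#'   inside each block.
#' @param alpha Octave low-frequency channel ratio in `[0, 1)`; 0 recovers
#'   vanilla convolutions.
#' @param gru_hidden Hidden state size of each GRU direction.
#' @param dropout_rate Dropout rate applied to the pooled frame sequence
#'   before the GRU and to the GRU output before the classifier.
#' @param num_classes Output classes per frame (2: frame contains a fetal
#'   QRS complex or not).
#' @param normalize Standardize each window per channel (zero mean, unit
#'   variance) before the network sees it.
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and variance floor.
#' @return A list of class `octqrs_config`.
#' @export
network_config <- function(in_channels = 4L,
                           window_length = 1000L,
                           frames_per_window = 10L,
                           block_filters = c(64L, 128L, 128L),
                           block_kernel_lengths = c(8L, 5L, 3L),
                           alpha = 0,
                           gru_hidden = 32L,
                           dropout_rate = 0.4,
                           num_classes = 2L,
                           normalize = TRUE,
                           bn_momentum = 0.1,
                           bn_eps = 1e-5) {
  cfg <- list(in_channels = as.integer(in_channels),
              window_length = as.integer(window_length),
              frames_per_window = as.integer(frames_per_window),
              frame_length = as.integer(window_length / frames_per_window),
              block_filters = as.integer(block_filters),
              block_kernel_lengths = as.integer(block_kernel_lengths),
              alpha = alpha, gru_hidden = as.integer(gru_hidden),
              dropout_rate = dropout_rate, num_classes = as.integer(num_classes),
              normalize = isTRUE(normalize),
              bn_momentum = bn_momentum, bn_eps = bn_eps)
  validate_config(cfg)
  structure(cfg, class = "octqrs_config")
}

validate_config <- function(cfg) {
  if (cfg$window_length != cfg$frames_per_window * cfg$frame_length)
    abort("window_length must equal frames_per_window * frame_length")
  if (cfg$window_length %% 2L != 0L)
    abort("window_length must be even (octave factorization halves it)")
  check_alpha(cfg$alpha)
  if (cfg$alpha >= 1) abort("alpha must be < 1: the trunk output needs a high-frequency branch")
  if (length(cfg$block_filters) != length(cfg$block_kernel_lengths) &&
      length(cfg$block_kernel_lengths) < 1L)
    abort("block_kernel_lengths must be non-empty")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  invisible(cfg)
}

modify_config <- function(cfg, ...) {
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$frame_length <- as.integer(cfg$window_length / cfg$frames_per_window)
  validate_config(cfg)
  cfg
}

#' A reduced preset of the detector for CPU-scale experiments
#'
#' Same topology as [network_config()] (three residual blocks, kernels
#' 8/5/3, octave convolutions, bidirectional GRU, shared softmax) with
#' 8/16/16 filters instead of 64/128/128, sized so that a full training run
#' on synthetic data completes in minutes on a single CPU core.
#'
#' @param ... Overrides passed on to [network_config()].
#' @export
network_config_reduced <- function(...) {
  network_config(block_filters = c(8L, 16L, 16L), ...)
}

glorot_mat <- function(nrow, ncol) {
  a <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -a, a), nrow, ncol)
}

new_bn <- function(channels) {
  if (channels == 0L) return(NULL)
  list(gamma = rep(1, channels), beta = numeric(channels),
       running_mean = numeric(channels), running_var = rep(1, channels))
}

#' Build the detector
#'
#' Instantiates all trainable weights of the configured network with
#' Glorot-uniform initialization (biases and batch-norm shifts zero, batch
#' norm scales one). Weight shapes depend on `alpha` through the octave
#' channel split, but the total parameter count does not.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for the initialization draw.
#' @return An object of class `octqrs_network`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- conv_plan(config)
  blocks <- vector("list", length(config$block_filters))
  for (b in seq_along(blocks)) blocks[[b]] <- list(convs = list(), shortcut = NULL)
  for (p in plan) {
    layer <- octconv_layer(p$k, p$c_in, p$c_out, p$alpha_in, p$alpha_out, init = "xavier")
    if (p$role == "conv") {
      so <- split_channels(p$c_out, p$alpha_out)
      blocks[[p$block]]$convs[[length(blocks[[p$block]]$convs) + 1L]] <-
        list(layer = layer,
             bn = list(high = new_bn(so[["high"]]), low = new_bn(so[["low"]])))
    } else {
      blocks[[p$block]]$shortcut <- layer
    }
  }
  d_in <- config$block_filters[length(config$block_filters)]
  h <- config$gru_hidden
  new_gru_dir <- function() list(
    Wr = glorot_mat(h, d_in), Ur = glorot_mat(h, h), br = numeric(h),
    Wz = glorot_mat(h, d_in), Uz = glorot_mat(h, h), bz = numeric(h),
    Wh = glorot_mat(h, d_in), Uh = glorot_mat(h, h), bh = numeric(h))
  net <- list(config = config,
              blocks = blocks,
              gru = list(fwd = new_gru_dir(), bwd = new_gru_dir()),
              cls = list(W = glorot_mat(config$num_classes, 2L * h),
                         b = numeric(config$num_classes)))
  structure(net, class = "octqrs_network")
}

#' Count trainable parameters of a built network
#' @param net An `octqrs_network`.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "octqrs_network"))
  n <- 0
  for (blk in net$blocks) {
    for (cv in blk$convs) {
      n <- n + octconv_n_params(cv$layer)
      for (br in cv$bn) if (!is.null(br)) n <- n + length(br$gamma) + length(br$beta)
    }
    n <- n + octconv_n_params(blk$shortcut)
  }
  for (dir in net$gru) for (w in dir) n <- n + length(w)
  n + length(net$cls$W) + length(net$cls$b)
}

#' Pool trunk features into per-frame vectors
#'
#' Splits a `[channels x time]` feature map into `frames` equal parts and
#' averages each part over time, producing one feature vector per 100-ms
#' decision frame.
#'
#' @param features `[channels x time]` matrix or `[channels x time x batch]`
#'   array; the time dimension must be divisible by `frames`.
#' @param frames Number of segments (default 10).
#' @return `[channels x frames]` matrix (or `[channels x frames x batch]`).
#' @export
segment_pool <- function(features, frames = 10L) {
  x3 <- as_fmap3(features)
  d <- dim(x3)
  if (d[2] %% frames != 0L)
    abort(sprintf("feature length %d is not divisible into %d frames", d[2], frames))
  flen <- d[2] %/% frames
  z <- aperm(array(x3, c(d[1], flen, frames, d[3])), c(2L, 1L, 3L, 4L))
  pooled <- colMeans(z)  # averages the within-frame axis
  drop_batch_like(pooled, features)
}

segment_pool_backward <- function(dpooled, time_length) {
  d <- dim(dpooled)
  flen <- time_length %/% d[2]
  dpooled[, rep(seq_len(d[2]), each = flen), , drop = FALSE] / flen
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One gated-recurrent-unit step
#'
#' Computes the reset gate `r`, update gate `z`, candidate state and the
#' convex combination
#' `h_t = (1 - z_t) * h_{t-1} + z_t * tanh(W x_t + U (r_t * h_{t-1}) + b)`.
#'
#' @param x_t Input vector (or `[input x batch]` matrix).
#' @param h_prev Previous hidden state vector (or `[hidden x batch]` matrix).
#' @param params List with `Wr, Ur, br, Wz, Uz, bz, Wh, Uh, bh`.
#' @return The new hidden state, same shape as `h_prev`.
#' @export
gru_cell <- function(x_t, h_prev, params) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev)
  if (nrow(params$Wr) != nrow(h_prev) || ncol(params$Wr) != nrow(x_t))
    abort("gru_cell: parameter shapes do not match the input/hidden dimensions")
  st <- gru_step(x_t, h_prev, params)
  st$h
}

gru_step <- function(x_t, h_prev, p) {
  r <- sigmoid(p$Wr %*% x_t + p$Ur %*% h_prev + p$br)
  z <- sigmoid(p$Wz %*% x_t + p$Uz %*% h_prev + p$bz)
  rh <- r * h_prev
  hc <- tanh(p$Wh %*% x_t + p$Uh %*% rh + p$bh)
  h <- (1 - z) * h_prev + z * hc
  list(h = h, r = r, z = z, hc = hc, rh = rh)
}

gru_seq_forward <- function(x, p, keep_cache = FALSE) {
  d <- dim(x)  # (D, steps, B)
  h <- matrix(0, nrow(p$Ur), d[3])
  out <- array(0, c(nrow(p$Ur), d[2], d[3]))
  cache <- if (keep_cache) vector("list", d[2])
  for (t in seq_len(d[2])) {
    x_t <- matrix(x[, t, ], d[1], d[3])
    st <- gru_step(x_t, h, p)
    if (keep_cache) cache[[t]] <- c(st, list(x_t = x_t, h_prev = h))
    h <- st$h
    out[, t, ] <- h
  }
  list(out = out, cache = cache)
}

gru_seq_backward <- function(p, cache, dout) {
  d <- dim(dout)  # (H, steps, B)
  zmat <- function(m) matrix(0, nrow(m), ncol(m))
  g <- list(Wr = zmat(p$Wr), Ur = zmat(p$Ur), br = numeric(length(p$br)),
            Wz = zmat(p$Wz), Uz = zmat(p$Uz), bz = numeric(length(p$bz)),
            Wh = zmat(p$Wh), Uh = zmat(p$Uh), bh = numeric(length(p$bh)))
  dx <- array(0, c(ncol(p$Wr), d[2], d[3]))
  dh_carry <- matrix(0, d[1], d[3])
  for (t in rev(seq_len(d[2]))) {
    st <- cache[[t]]
    dh <- matrix(dout[, t, ], d[1], d[3]) + dh_carry
    dz <- dh * (st$hc - st$h_prev)
    dhc <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dhc_pre <- dhc * (1 - st$hc^2)
    g$Wh <- g$Wh + dhc_pre %*% t(st$x_t)
    g$Uh <- g$Uh + dhc_pre %*% t(st$rh)
    g$bh <- g$bh + rowSums(dhc_pre)
    drh <- t(p$Uh) %*% dhc_pre
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dr_pre <- dr * st$r * (1 - st$r)
    dz_pre <- dz * st$z * (1 - st$z)
    g$Wr <- g$Wr + dr_pre %*% t(st$x_t); g$Ur <- g$Ur + dr_pre %*% t(st$h_prev)
    g$br <- g$br + rowSums(dr_pre)
    g$Wz <- g$Wz + dz_pre %*% t(st$x_t); g$Uz <- g$Uz + dz_pre %*% t(st$h_prev)
    g$bz <- g$bz + rowSums(dz_pre)
    dx[, t, ] <- t(p$Wr) %*% dr_pre + t(p$Wz) %*% dz_pre + t(p$Wh) %*% dhc_pre
    dh_carry <- dh_prev + t(p$Ur) %*% dr_pre + t(p$Uz) %*% dz_pre
  }
  list(dx = dx, grads = g)
}
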