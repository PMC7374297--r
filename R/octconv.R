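#' Feature maps and the 1-D octave convolution operator
#'
#' A *feature map* is a real-valued array indexed `[channel, time]`, with an
#' optional trailing batch axis (`[channel, time, batch]`). Octave convolution
#' factorizes a feature map along the channel axis into a full-resolution
#' *high-frequency* group and a half-resolution *low-frequency* group, the
#' fraction of channels assigned to the low group being the ratio `alpha`.
#' Four kernel groups exchange information between the two resolutions; at
#' `alpha = 0` the operator degenerates to a vanilla 1-D convolution.
#'
#' @name octconv
NULL

# Coerce a matrix [C x T] or array [C x T x B] to the 3-d batch form,
# remembering whether a batch axis was present.
as_fmap3 <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    array(x, c(dim(x), 1L))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    x
  } else {
    abort("a feature map must be a [channel x time] matrix or a [channel x time x batch] array")
  }
}

drop_batch_like <- function(y, x) {
  if (is.matrix(x)) matrix(y, nrow = dim(y)[1], ncol = dim(y)[2]) else y
}

#' Halve a feature map's temporal resolution by average pooling
#'
#' Average pooling with kernel size 2 and stride 2: each output sample is the
#' mean of two consecutive input samples. This is the down-sampling primitive
#' of the octave factorization, so the input length must be even.
#'
#' @param x A feature map: `[channel x time]` matrix or `[channel x time x batch]` array.
#' @return A feature map of the same form with half the temporal length.
#' @examples
#' average_pool_halve(matrix(c(1, 3, 5, 7), nrow = 1))  # 2, 6
#' @export
average_pool_halve <- function(x) {
  x3 <- as_fmap3(x)
  T <- dim(x3)[2]
  if (T %% 2L != 0L)
    abort("octave factorization requires even window lengths; got an odd temporal length")
  drop_batch_like(pool_halve_cpp(x3), x)
}

#' Double a feature map's temporal resolution by nearest-neighbour upsampling
#'
#' Each input sample is repeated twice consecutively (`out[t] = in[t %/% 2]`
#' in 0-based indexing), the up-sampling primitive of the octave
#' factorization. Constant signals are fixed points of
#' `upsample_double(average_pool_halve(x))`.
#'
#' @inheritParams average_pool_halve
#' @return A feature map of the same form with twice the temporal length.
#' @export
upsample_double <- function(x) {
  x3 <- as_fmap3(x)
  drop_batch_like(upsample2_cpp(x3), x)
}

#' Length-preserving 1-D convolution (cross-correlation)
#'
#' Linear cross-correlation over channels with stride 1 and zero padding that
#' preserves the temporal length. For odd kernel lengths the padding is
#' symmetric; for even lengths `k` the signal is padded `k/2 - 1` on the left
#' and `k/2` on the right. No nonlinearity is applied.
#'
#' @inheritParams average_pool_halve
#' @param weights Kernel array `[out_channels x in_channels x kernel_length]`.
#' @param bias Per-output-channel offsets; defaults to zero.
#' @return A feature map with `out_channels` channels and the input's length.
#' @export
conv1d <- function(x, weights, bias = NULL) {
  x3 <- as_fmap3(x)
  if (!is.array(weights) || length(dim(weights)) != 3L)
    abort("weights must be a 3-d array [out_channels x in_channels x kernel_length]")
  if (dim(x3)[1] != dim(weights)[2])
    abort(sprintf("input has %d channels but weights expect %d",
                  dim(x3)[1], dim(weights)[2]))
  k <- dim(weights)[3]
  if (is.null(bias)) bias <- numeric(dim(weights)[1])
  y <- conv1d_fwd_cpp(x3, weights, as.numeric(bias), pad_left_for(k))
  drop_batch_like(y, x)
}

pad_left_for <- function(k) as.integer(floor((k - 1) / 2))

#' Split channels between the high- and low-frequency groups
#'
#' @param channels Total channel count.
#' @param alpha Fraction of channels assigned to the low-frequency group,
#'   in `[0, 1]`. The low group gets `round(alpha * channels)` channels.
#' @return Integer vector `c(high, low)`.
#' @export
split_channels <- function(channels, alpha) {
  check_alpha(alpha)
  c_low <- as.integer(round(alpha * channels))
  c(high = channels - c_low, low = c_low)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    abort("alpha must be a single number in [0, 1]")
  invisible(alpha)
}

#' Construct a frequency-factorized feature map
#'
#' Pairs a full-resolution high-frequency map with a half-resolution
#' low-frequency map. Either branch may be `NULL` exactly when `alpha` is 0
#' (no low branch) or 1 (no high branch).
#'
#' @param high Feature map of the high-frequency group, or `NULL`.
#' @param low Feature map of the low-frequency group (half length), or `NULL`.
#' @param alpha Low-frequency channel ratio in `[0, 1]`.
#' @return An object of class `freq_map` with fields `high`, `low`, `alpha`.
#' @export
freq_map <- function(high, low, alpha) {
  check_alpha(alpha)
  if (is.null(low) && alpha != 0)
    abort("the low branch may be empty only when alpha is 0")
  if (is.null(high) && alpha != 1)
    abort("the high branch may be empty only when alpha is 1")
  if (!is.null(high) && !is.null(low)) {
    h <- as_fmap3(high); l <- as_fmap3(low)
    if (2L * dim(l)[2] != dim(h)[2])
      abort("low branch length times 2 must equal the high branch length")
  }
  structure(list(high = high, low = low, alpha = alpha), class = "freq_map")
}

#' Factorize a full-resolution feature map into frequency groups
#'
#' The first `high` channels stay at full resolution; the remaining
#' `round(alpha * channels)` channels are average-pooled to half resolution.
#' Used at the entry of an octave network (`alpha_in = 0` boundary handles
#' this internally); exposed for testing and composition.
#'
#' @inheritParams average_pool_halve
#' @inheritParams split_channels
#' @export
oct_split <- function(x, alpha) {
  x3 <- as_fmap3(x)
  sp <- split_channels(dim(x3)[1], alpha)
  high <- if (sp[1] > 0) drop_batch_like(x3[seq_len(sp[1]), , , drop = FALSE], x)
  low <- if (sp[2] > 0) {
    drop_batch_like(average_pool_halve(x3[sp[1] + seq_len(sp[2]), , , drop = FALSE]), x)
  }
  freq_map(high, low, alpha)
}

#' Merge a frequency-factorized map back to full resolution
#'
#' The low branch is nearest-neighbour upsampled and stacked under the high
#' branch along the channel axis.
#'
#' @param fm A `freq_map`.
#' @export
oct_merge <- function(fm) {
  stopifnot(inherits(fm, "freq_map"))
  if (is.null(fm$low)) return(fm$high)
  lo <- upsample_double(fm$low)
  if (is.null(fm$high)) return(lo)
  h3 <- as_fmap3(fm$high); l3 <- as_fmap3(lo)
  y <- array(0, c(dim(h3)[1] + dim(l3)[1], dim(h3)[2], dim(h3)[3]))
  y[seq_len(dim(h3)[1]), , ] <- h3
  y[dim(h3)[1] + seq_len(dim(l3)[1]), , ] <- l3
  drop_batch_like(y, fm$high)
}

#' Construct an octave convolution layer
#'
#' Holds the four kernel groups (high-to-high, high-to-low, low-to-high,
#' low-to-low) plus per-output-channel biases. The total weight count equals
#' `in_channels * out_channels * kernel_length` for every `(alpha_in,
#' alpha_out)` pair: splitting channels between frequency groups conserves
#' parameters. Groups touching an empty branch have zero size.
#'
#' @param kernel_length Kernel length `k` (>= 1).
#' @param in_channels,out_channels Channel counts.
#' @param alpha_in,alpha_out Low-frequency ratios of the input and output maps.
#' @param init `"xavier"` for Glorot-uniform initialization, `"zeros"` for
#'   all-zero weights (useful in tests).
#' @return An object of class `octconv_layer`.
#' @export
octconv_layer <- function(kernel_length, in_channels, out_channels,
                          alpha_in = 0, alpha_out = 0,
                          init = c("xavier", "zeros")) {
  init <- match.arg(init)
  check_alpha(alpha_in); check_alpha(alpha_out)
  stopifnot(kernel_length >= 1, in_channels >= 1, out_channels >= 1)
  si <- split_channels(in_channels, alpha_in)
  so <- split_channels(out_channels, alpha_out)
  mk <- function(co, ci) {
    if (co == 0L || ci == 0L) return(array(0, c(co, ci, kernel_length)))
    w <- array(0, c(co, ci, kernel_length))
    if (init == "xavier") {
      # Glorot-uniform with the layer's full fan (receptive field x channels)
      a <- sqrt(6 / ((in_channels + out_channels) * kernel_length))
      w[] <- runif(length(w), -a, a)
    }
    w
  }
  structure(list(
    kernel_length = as.integer(kernel_length),
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    alpha_in = alpha_in, alpha_out = alpha_out,
    W_hh = mk(so[1], si[1]), W_hl = mk(so[2], si[1]),
    W_lh = mk(so[1], si[2]), W_ll = mk(so[2], si[2]),
    b_h = numeric(so[1]), b_l = numeric(so[2])
  ), class = "octconv_layer")
}

#' Number of trainable parameters of an octave convolution layer
#' @param layer An `octconv_layer`.
#' @param bias Include bias terms in the count.
#' @export
octconv_n_params <- function(layer, bias = TRUE) {
  n <- length(layer$W_hh) + length(layer$W_hl) +
       length(layer$W_lh) + length(layer$W_ll)
  if (bias) n <- n + length(layer$b_h) + length(layer$b_l)
  n
}

#' Apply an octave convolution
#'
#' Computes the two output branches
#' \deqn{Y^H = f(X^H; W^{H\to H}) + \mathrm{upsample}(f(X^L; W^{L\to H}), 2)}
#' \deqn{Y^L = f(X^L; W^{L\to L}) + f(\mathrm{pool}(X^H, 2); W^{H\to L})}
#' where `f` is a length-preserving 1-D convolution. Absent branches
#' contribute nothing; biases are added once per output channel after the two
#' paths are summed. With `alpha_in = alpha_out = 0` the result equals
#' [conv1d()] with the same (concatenated) kernel.
#'
#' @param x A `freq_map` whose `alpha` equals `layer$alpha_in`.
#' @param layer An [octconv_layer()].
#' @return A `freq_map` with `alpha = layer$alpha_out`; the high-branch
#'   length equals the input high-branch length.
#' @export
octconv_forward <- function(x, layer) {
  stopifnot(inherits(x, "freq_map"), inherits(layer, "octconv_layer"))
  if (!isTRUE(all.equal(x$alpha, layer$alpha_in)))
    abort(sprintf("input map has alpha %.3f but the layer expects alpha_in %.3f",
                  x$alpha, layer$alpha_in))
  so <- split_channels(layer$out_channels, layer$alpha_out)
  if (so[2] > 0 && !is.null(x$high) && dim(as_fmap3(x$high))[2] %% 2L != 0L)
    abort("octave factorization requires even window lengths on the high branch")
  y_h <- y_l <- NULL
  # the per-channel bias rides along the first contributing path (nearest
  # upsampling preserves per-channel constants, so this is exact)
  if (so[1] > 0) {
    if (!is.null(x$high)) {
      y_h <- conv1d(x$high, layer$W_hh, layer$b_h)
      if (!is.null(x$low))
        y_h <- y_h + upsample_double(conv1d(x$low, layer$W_lh))
    } else {
      y_h <- upsample_double(conv1d(x$low, layer$W_lh, layer$b_h))
    }
  }
  if (so[2] > 0) {
    if (!is.null(x$low)) {
      y_l <- conv1d(x$low, layer$W_ll, layer$b_l)
      if (!is.null(x$high))
        y_l <- y_l + conv1d(average_pool_halve(x$high), layer$W_hl)
    } else {
      y_l <- conv1d(average_pool_halve(x$high), layer$W_hl, layer$b_l)
    }
  }
  freq_map(y_h, y_l, layer$alpha_out)
}

#' Concatenate an octave layer's kernels into one vanilla kernel
#'
#' Stacks the four groups into a single `[out x in x k]` array (high channels
#' first on both axes). At `alpha_in = alpha_out = 0` this is exactly the
#' vanilla kernel the layer reduces to.
#'
#' @param layer An `octconv_layer`.
#' @export
octconv_as_vanilla <- function(layer) {
  si <- split_channels(layer$in_channels, layer$alpha_in)
  so <- split_channels(layer$out_channels, layer$alpha_out)
  w <- array(0, c(layer$out_channels, layer$in_channels, layer$kernel_length))
  if (so[1] > 0 && si[1] > 0) w[seq_len(so[1]), seq_len(si[1]), ] <- layer$W_hh
  if (so[2] > 0 && si[1] > 0) w[so[1] + seq_len(so[2]), seq_len(si[1]), ] <- layer$W_hl
  if (so[1] > 0 && si[2] > 0) w[seq_len(so[1]), si[1] + seq_len(si[2]), ] <- layer$W_lh
  if (so[2] > 0 && si[2] > 0) w[so[1] + seq_len(so[2]), si[1] + seq_len(si[2]), ] <- layer$W_ll
  w
}
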