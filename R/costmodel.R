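#' Analytic compute and memory cost of 1-D (octave) convolutions
#'
#' Multiply-accumulate (MAC) and feature-storage accounting for vanilla and
#' octave 1-D convolutions, per layer and for the whole detector. One FLOP is
#' counted per multiply-accumulate; bias additions, batch normalization,
#' ReLU, pooling and resampling are excluded. Feature memory is counted in
#' stored values: `l*(1-alpha)*c + (l/2)*alpha*c` per layer output.
#'
#' @name costmodel
NULL

#' FLOPs of a vanilla 1-D convolution layer
#'
#' `l * k * c_in * c_out` multiply-accumulates for a length-preserving
#' stride-1 convolution of a length-`l` input.
#'
#' @param length Temporal length `l` of the input feature map.
#' @param kernel_length Kernel length `k`.
#' @param in_channels,out_channels Channel counts.
#' @param alpha_in,alpha_out Must both be 0; nonzero ratios belong to
#'   [octconv_flops()].
#' @return A count of multiply-accumulate operations.
#' @export
conv_flops <- function(length, kernel_length, in_channels, out_channels,
                       alpha_in = 0, alpha_out = 0) {
  if (alpha_in != 0 || alpha_out != 0)
    abort("conv_flops is the vanilla (alpha = 0) cost; use octconv_flops for nonzero alpha")
  stopifnot(length >= 1, kernel_length >= 1, in_channels >= 1, out_channels >= 1)
  length * kernel_length * in_channels * out_channels
}

#' FLOPs of a 1-D octave convolution layer
#'
#' Sum of the four information paths, with the input split governed by
#' `alpha_in` and the output split by `alpha_out`:
#' \deqn{HH: l k (1-\alpha_{in})(1-\alpha_{out}) c_{in} c_{out}}
#' \deqn{HL: (l/2) k (1-\alpha_{in}) \alpha_{out} c_{in} c_{out}}
#' \deqn{LH: (l/2) k \alpha_{in} (1-\alpha_{out}) c_{in} c_{out}}
#' \deqn{LL: (l/2) k \alpha_{in} \alpha_{out} c_{in} c_{out}}
#' At `alpha_in = alpha_out = 0` this equals [conv_flops()]; at equal alphas
#' it reduces to the closed form `l*k*c_in*c_out*(1 - alpha + alpha^2/2)`.
#'
#' @inheritParams conv_flops
#' @export
octconv_flops <- function(length, kernel_length, in_channels, out_channels,
                          alpha_in = 0, alpha_out = 0) {
  check_alpha(alpha_in); check_alpha(alpha_out)
  l <- length; k <- kernel_length; cc <- in_channels * out_channels
  hh <- l * k * (1 - alpha_in) * (1 - alpha_out) * cc
  hl <- (l / 2) * k * (1 - alpha_in) * alpha_out * cc
  lh <- (l / 2) * k * alpha_in * (1 - alpha_out) * cc
  ll <- (l / 2) * k * alpha_in * alpha_out * cc
  hh + hl + lh + ll
}

#' Relative compute cost of octave versus vanilla convolution
#'
#' The per-layer FLOPs ratio at equal input/output split,
#' `1 - alpha * (1 - alpha/2)`; strictly decreasing on `[0, 1)`.
#'
#' @param alpha Low-frequency channel ratio in `[0, 1]` (vectorized).
#' @export
flops_ratio <- function(alpha) {
  vapply(alpha, check_alpha, numeric(1))
  1 - alpha * (1 - alpha / 2)
}

#' Relative feature-memory cost of the octave representation
#'
#' Storing `(1-alpha)*c` channels at full length and `alpha*c` channels at
#' half length costs `1 - alpha/2` of full-resolution storage.
#'
#' @inheritParams flops_ratio
#' @export
memory_ratio <- function(alpha) {
  vapply(alpha, check_alpha, numeric(1))
  1 - alpha / 2
}

oct_memory_units <- function(length, out_channels, alpha_out) {
  length * (1 - alpha_out) * out_channels + (length / 2) * alpha_out * out_channels
}

#' Per-layer and total cost of the fetal-QRS detector
#'
#' Walks the detector configuration (three residual blocks of three octave
#' convolutions plus a 1x1 shortcut convolution per block, then the
#' bidirectional GRU head and the shared frame classifier) and returns one
#' row per costed layer. Convolution costs follow [octconv_flops()] with the
#' boundary splits `alpha_in = 0` on the first convolution and
#' `alpha_out = 0` on the last; the GRU head costs
#' `2 directions x timesteps x 3 gates x (input*hidden + hidden^2)` MACs and
#' the shared classifier `timesteps * 2*hidden_bi * classes` MACs.
#'
#' @param config A [network_config()].
#' @return A tibble of class `octqrs_cost` with columns `layer`, `block`,
#'   `role`, `kernel_length`, `in_channels`, `out_channels`, `alpha_in`,
#'   `alpha_out`, `flops`, `params`, `memory_units`. Totals and ratios are
#'   available through [glance()].
#' @examples
#' glance(network_cost(network_config()))
#' @export
network_cost <- function(config = network_config()) {
  plan <- conv_plan(config)
  l <- config$window_length
  rows <- purrr::map_dfr(plan, function(p) {
    tibble(
      layer = p$name, block = p$block, role = p$role,
      kernel_length = p$k, in_channels = p$c_in, out_channels = p$c_out,
      alpha_in = p$alpha_in, alpha_out = p$alpha_out,
      flops = octconv_flops(l, p$k, p$c_in, p$c_out, p$alpha_in, p$alpha_out),
      params = p$c_in * p$c_out * p$k + p$c_out + 2 * p$c_out,  # kernels + bias + BN scale/shift
      memory_units = oct_memory_units(l, p$c_out, p$alpha_out)
    )
  })
  # shortcut convolutions carry no batch normalization of their own
  rows$params[rows$role == "shortcut"] <-
    rows$params[rows$role == "shortcut"] - 2 * rows$out_channels[rows$role == "shortcut"]

  d_in <- config$block_filters[length(config$block_filters)]
  h <- config$gru_hidden
  steps <- config$frames_per_window
  gru_flops <- 2 * steps * 3 * (d_in * h + h * h)
  gru_params <- 2 * 3 * (d_in * h + h * h + h)
  cls_flops <- steps * (2 * h) * config$num_classes
  cls_params <- (2 * h) * config$num_classes + config$num_classes
  rows <- dplyr::bind_rows(
    rows,
    tibble(layer = "bigru", block = NA_integer_, role = "recurrent",
           kernel_length = NA_integer_, in_channels = d_in, out_channels = 2L * h,
           alpha_in = NA_real_, alpha_out = NA_real_,
           flops = gru_flops, params = gru_params, memory_units = steps * 2 * h),
    tibble(layer = "classifier", block = NA_integer_, role = "classifier",
           kernel_length = NA_integer_, in_channels = 2L * h,
           out_channels = config$num_classes,
           alpha_in = NA_real_, alpha_out = NA_real_,
           flops = cls_flops, params = cls_params,
           memory_units = steps * config$num_classes)
  )
  structure(rows, class = c("octqrs_cost", class(rows)),
            config = config, alpha = config$alpha)
}

#' @rdname network_cost
#' @param x An `octqrs_cost` table.
#' @param ... Unused.
#' @export
glance.octqrs_cost <- function(x, ...) {
  config <- attr(x, "config")
  conv <- x$role %in% c("conv", "shortcut")
  baseline <- network_cost(modify_config(config, alpha = 0))
  tibble(
    alpha = attr(x, "alpha"),
    cnn_gflops = sum(x$flops[conv]) / 1e9,
    head_gflops = sum(x$flops[!conv]) / 1e9,
    total_gflops = sum(x$flops) / 1e9,
    total_params = sum(x$params),
    memory_units = sum(x$memory_units[conv]),
    flops_ratio_vs_baseline = sum(x$flops[conv]) /
      sum(baseline$flops[baseline$role %in% c("conv", "shortcut")]),
    memory_ratio_vs_baseline = sum(x$memory_units[conv]) /
      sum(baseline$memory_units[baseline$role %in% c("conv", "shortcut")])
  )
}

# Layer-by-layer convolution plan of the trunk: three blocks of three
# convolutions (kernel lengths per block_kernel_lengths) plus a 1x1 shortcut,
# with the octave boundary pattern (first conv alpha_in = 0, last conv
# alpha_out = 0, shortcuts bridging each block's input to its output split).
conv_plan <- function(config) {
  a <- config$alpha
  nb <- length(config$block_filters)
  ks <- config$block_kernel_lengths
  plan <- list()
  c_prev <- config$in_channels
  n_layer <- 0L
  for (b in seq_len(nb)) {
    c_out <- config$block_filters[b]
    a_block_in <- if (b == 1L) 0 else a
    c_in <- c_prev
    for (j in seq_along(ks)) {
      n_layer <- n_layer + 1L
      is_first <- b == 1L && j == 1L
      is_last <- b == nb && j == length(ks)
      plan[[length(plan) + 1L]] <- list(
        name = sprintf("block%d_conv%d", b, j), block = b, role = "conv",
        k = ks[j], c_in = c_in, c_out = c_out,
        alpha_in = if (is_first) 0 else a,
        alpha_out = if (is_last) 0 else a)
      c_in <- c_out
    }
    a_block_out <- if (b == nb) 0 else a
    plan[[length(plan) + 1L]] <- list(
      name = sprintf("block%d_shortcut", b), block = b, role = "shortcut",
      k = 1L, c_in = c_prev, c_out = c_out,
      alpha_in = a_block_in, alpha_out = a_block_out)
    c_prev <- c_out
  }
  plan
}
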