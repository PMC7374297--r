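#' 1-D gradient-weighted class activation mapping
#'
#' Explains a frame decision of the detector by weighting each channel of
#' the final convolutional feature map (the 128 x 1000 activation entering
#' the per-frame pooling stage) with the time-averaged gradient of the
#' target frame's pre-softmax class score, and rectifying the weighted sum:
#' `L_c = ReLU(sum_k alpha_k^c A^k)`. The final feature map is at full
#' temporal resolution, so the attention trace aligns sample-by-sample with
#' the input window. One forward and one backward pass suffice.
#'
#' @name gradcam
NULL

#' Per-channel Grad-CAM weights from a score gradient
#'
#' Averages the gradient of the class score over the time positions of the
#' target frame (or over the whole window), one weight per channel.
#'
#' @param score_gradient `[channels x time]` gradient of the target class
#'   score with respect to the final convolutional feature map.
#' @param frame_span Integer vector of time indices to average over
#'   (1-based); defaults to all positions.
#' @return Numeric vector of per-channel weights.
#' @export
channel_weights <- function(score_gradient, frame_span = NULL) {
  stopifnot(is.matrix(score_gradient))
  if (is.null(frame_span)) frame_span <- seq_len(ncol(score_gradient))
  rowMeans(score_gradient[, frame_span, drop = FALSE])
}

#' Compute a Grad-CAM attention trace for one frame decision
#'
#' @param model An `octqrs_network` or `octqrs_fit`.
#' @param window A `[channels x window_length]` signal window (raw; the
#'   model's own normalization is applied).
#' @param target_frame Frame whose score is explained, 0-based in
#'   `[0, frames_per_window)`.
#' @param target_class Class of interest: 1 (fetal QRS present, default)
#'   or 0.
#' @param span `"frame"` averages gradients over the 100 samples of the
#'   target frame; `"window"` averages over the whole window.
#' @return An object of class `octqrs_attention`: list with `values`
#'   (non-negative, one per input sample), `weights` (per-channel),
#'   `target_frame`, `target_class`.
#' @export
grad_cam <- function(model, window, target_frame, target_class = 1L,
                     span = c("frame", "window")) {
  if (inherits(model, "octqrs_fit")) model <- model$net
  stopifnot(inherits(model, "octqrs_network"))
  span <- match.arg(span)
  cfg <- model$config
  if (target_frame < 0L || target_frame >= cfg$frames_per_window)
    abort(sprintf("target_frame must be in [0, %d)", cfg$frames_per_window))
  if (!target_class %in% c(0L, 1L)) abort("target_class must be 0 or 1")
  x <- windows_to_array(window, cfg)
  if (cfg$normalize) x <- standardize_windows(x)
  tr <- trunk_forward(model, x, train = FALSE)
  A <- tr$out  # (channels, time, 1)
  hd <- head_forward(model, A, train = FALSE, keep_cache = TRUE)
  dlogits <- array(0, dim(hd$logits))
  dlogits[target_class + 1L, target_frame + 1L, 1] <- 1
  dA <- head_backward(model, hd$cache, dlogits)$dA
  flen <- cfg$frame_length
  fspan <- if (span == "frame") {
    target_frame * flen + seq_len(flen)
  } else NULL
  w <- channel_weights(matrix(dA, dim(dA)[1]), fspan)
  Amat <- matrix(A, dim(A)[1])
  values <- pmax(colSums(Amat * w), 0)
  structure(list(values = values, weights = w,
                 target_frame = as.integer(target_frame),
                 target_class = as.integer(target_class),
                 logits = hd$logits[, , 1]),
            class = "octqrs_attention")
}

#' @export
print.octqrs_attention <- function(x, ...) {
  cat(sprintf("<octqrs_attention: frame %d, class %d, peak at sample %d>\n",
              x$target_frame, x$target_class, which.max(x$values) - 1L))
  invisible(x)
}

#' @export
as_tibble.octqrs_attention <- function(x, ...) {
  tibble(sample = seq_along(x$values) - 1L, attention = x$values,
         target_frame = x$target_frame, target_class = x$target_class)
}

#' Whole-window attention by summing frame-wise maps
#'
#' Sums [grad_cam()] traces of the given class over all frames (or a
#' subset), producing the whole-signal attention trace used to visualize
#' where the detector looks across a full 1-second window.
#'
#' @inheritParams grad_cam
#' @param frames 0-based frames to include; defaults to all.
#' @export
grad_cam_window <- function(model, window, target_class = 1L, frames = NULL,
                            span = "frame") {
  if (inherits(model, "octqrs_fit")) model <- model$net
  cfg <- model$config
  if (is.null(frames)) frames <- seq_len(cfg$frames_per_window) - 1L
  maps <- lapply(frames, function(f)
    grad_cam(model, window, f, target_class, span)$values)
  structure(list(values = Reduce(`+`, maps), weights = NULL,
                 target_frame = NA_integer_,
                 target_class = as.integer(target_class)),
            class = "octqrs_attention")
}
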