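#' Abdominal ECG recordings
#'
#' A recording holds a 4-channel signal sampled at 1000 Hz (microvolts,
#' one column per channel) together with the fetal QRS annotations as
#' strictly increasing 0-based sample indices.
#'
#' @param signals Numeric matrix `[samples x 4]` in microvolts.
#' @param fqrs Integer vector of strictly increasing 0-based fetal R-peak
#'   sample indices inside `[0, nrow(signals))`.
#' @param record_id Identifier string.
#' @param sampling_rate Samples per second.
#' @return An object of class `octqrs_recording`.
#' @export
recording <- function(signals, fqrs = integer(), record_id = "rec",
                      sampling_rate = 1000L) {
  signals <- as.matrix(signals)
  dimnames(signals) <- NULL
  storage.mode(signals) <- "double"
  fqrs <- as.integer(fqrs)
  if (any(!is.finite(signals))) abort("recording signals must be finite")
  if (length(fqrs)) {
    if (any(diff(fqrs) <= 0)) abort("fqrs annotations must be strictly increasing")
    if (min(fqrs) < 0L || max(fqrs) >= nrow(signals))
      abort("fqrs annotations must lie within [0, num_samples)")
  }
  structure(list(signals = signals, fqrs = fqrs,
                 record_id = as.character(record_id),
                 sampling_rate = as.integer(sampling_rate)),
            class = "octqrs_recording")
}

#' @export
print.octqrs_recording <- function(x, ...) {
  cat(sprintf("<octqrs_recording %s: %d samples x %d channels @ %d Hz, %d fetal QRS>\n",
              x$record_id, nrow(x$signals), ncol(x$signals),
              x$sampling_rate, length(x$fqrs)))
  invisible(x)
}

#' @export
as_tibble.octqrs_recording <- function(x, ...) {
  n <- nrow(x$signals)
  tibble(
    record_id = x$record_id,
    time_s = rep((seq_len(n) - 1L) / x$sampling_rate, ncol(x$signals)),
    channel = rep(paste0("ch", seq_len(ncol(x$signals))), each = n),
    amplitude_uv = as.vector(x$signals)
  )
}

#' Cut a recording into labeled 1-second windows
#'
#' Windows of `window_length` samples start at `0, stride, 2*stride, ...`
#' (trailing partial windows are dropped). Each window carries one binary
#' label per 100-ms frame: frame `j` is positive iff an annotation falls in
#' the half-open sample interval `[start + j*flen, start + (j+1)*flen)`.
#'
#' @param rec An [recording()].
#' @param stride Window stride in samples (default non-overlapping).
#' @param window_length Samples per window.
#' @param frames_per_window Label frames per window.
#' @return An object of class `octqrs_windows`: list with `x`
#'   (`[channels x window_length x n]` array), `y` (`[frames x n]` 0/1
#'   matrix) and `meta` (tibble of record id and start sample).
#' @export
extract_windows <- function(rec, stride = 1000L, window_length = 1000L,
                            frames_per_window = 10L) {
  stopifnot(inherits(rec, "octqrs_recording"), stride >= 1)
  n <- nrow(rec$signals)
  if (n < window_length) {
    warning("recording shorter than one window; returning no windows")
    return(new_windows(array(0, c(ncol(rec$signals), window_length, 0L)),
                       matrix(0L, frames_per_window, 0L),
                       tibble(record_id = character(), start = integer())))
  }
  starts <- seq(0L, n - window_length, by = as.integer(stride))
  flen <- window_length %/% frames_per_window
  x <- array(0, c(ncol(rec$signals), window_length, length(starts)))
  y <- matrix(0L, frames_per_window, length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    x[, , i] <- t(rec$signals[(s + 1L):(s + window_length), , drop = FALSE])
    ann <- rec$fqrs[rec$fqrs >= s & rec$fqrs < s + window_length]
    if (length(ann)) y[unique((ann - s) %/% flen) + 1L, i] <- 1L
  }
  new_windows(x, y, tibble(record_id = rec$record_id, start = starts))
}

new_windows <- function(x, y, meta) {
  structure(list(x = x, y = y, meta = meta), class = "octqrs_windows")
}

#' @export
print.octqrs_windows <- function(x, ...) {
  cat(sprintf("<octqrs_windows: %d windows of %d x %d, %d frames labeled, %.1f%% positive>\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2], length(x$y),
              if (length(x$y)) 100 * mean(x$y) else 0))
  invisible(x)
}

#' @export
as_tibble.octqrs_windows <- function(x, ...) {
  n <- dim(x$x)[3]
  frames <- nrow(x$y)
  dplyr::bind_cols(
    x$meta[rep(seq_len(n), each = frames), ],
    tibble(window = rep(seq_len(n), each = frames),
           frame = rep(seq_len(frames) - 1L, n),
           label = as.integer(x$y))
  )
}

#' Combine window sets
#' @param ... `octqrs_windows` objects with matching shapes.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  if (length(ws) == 1L && is.list(ws[[1]]) && !inherits(ws[[1]], "octqrs_windows"))
    ws <- ws[[1]]
  stopifnot(all(vapply(ws, inherits, logical(1), "octqrs_windows")))
  d <- dim(ws[[1]]$x)
  n <- sum(vapply(ws, function(w) dim(w$x)[3], integer(1)))
  x <- array(0, c(d[1], d[2], n))
  y <- matrix(0L, nrow(ws[[1]]$y), n)
  at <- 0L
  for (w in ws) {
    k <- dim(w$x)[3]
    if (k) {
      x[, , at + seq_len(k)] <- w$x
      y[, at + seq_len(k)] <- w$y
    }
    at <- at + k
  }
  new_windows(x, y, dplyr::bind_rows(lapply(ws, `[[`, "meta")))
}

#' Subset a window set
#' @param w An `octqrs_windows`.
#' @param idx Window indices to keep.
#' @export
subset_windows <- function(w, idx) {
  new_windows(w$x[, , idx, drop = FALSE], w$y[, idx, drop = FALSE], w$meta[idx, ])
}

#' Train/validation/test partition of PhysioNet 2013 set A record ids
#'
#' The fixed split used throughout: test `a01-a07`, validation `a08-a13`,
#' training the remaining records minus the seven with unreliable reference
#' annotations (`a33, a38, a47, a52, a54, a71, a74`).
#'
#' @param record_ids Character vector of ids following the `a01`-`a75`
#'   naming.
#' @return A list with elements `train`, `val`, `test` (disjoint character
#'   vectors).
#' @export
split_records <- function(record_ids) {
  record_ids <- as.character(record_ids)
  valid <- sprintf("a%02d", 1:75)
  bad <- setdiff(record_ids, valid)
  if (length(bad))
    abort(sprintf("unknown record id(s): %s (expected a01-a75)",
                  paste(bad, collapse = ", ")))
  excluded <- c("a33", "a38", "a47", "a52", "a54", "a71", "a74")
  test <- intersect(record_ids, sprintf("a%02d", 1:7))
  val <- intersect(record_ids, sprintf("a%02d", 8:13))
  train <- setdiff(record_ids, c(test, val, excluded))
  list(train = train, val = val, test = test)
}

#' Add bounded Gaussian noise to a recording
#'
#' Draws white Gaussian noise per channel, rescales it so its maximum
#' absolute value is 4 microvolts over the recording, multiplies by `level`
#' (levels 3, 6 and 9 emulate increasingly corrupted acquisitions) and adds
#' it to the signal. Annotations are untouched and the same seed reproduces
#' the same noise.
#'
#' @param rec An [recording()].
#' @param level Positive noise multiplier.
#' @param seed Integer seed.
#' @param base_range Maximum absolute value of the unscaled noise
#'   (microvolts).
#' @export
add_gaussian_noise <- function(rec, level, seed = 1L, base_range = 4) {
  stopifnot(inherits(rec, "octqrs_recording"), level > 0)
  set.seed(seed)
  noise <- matrix(rnorm(length(rec$signals)), nrow(rec$signals))
  noise <- noise / max(abs(noise)) * base_range
  out <- rec
  out$signals <- rec$signals + level * noise
  out
}

#' Add a synthetic motion artifact to a recording
#'
#' The signal is first min-max normalized to `[-1, 1]` per channel, then a
#' motion-like artifact is added: a sum of random-phase sinusoids between
#' 0.1 and 1 Hz plus sparse step transients, scaled by `severity`.
#' Annotations are untouched; the same seed reproduces the same artifact.
#'
#' @param rec An [recording()].
#' @param severity Non-negative artifact amplitude relative to the
#'   normalized signal (0 returns the normalized signal unchanged).
#' @param seed Integer seed.
#' @param n_components Number of sinusoidal components.
#' @param n_steps Expected number of step transients per minute.
#' @export
add_motion_artifact <- function(rec, severity, seed = 1L,
                                n_components = 8L, n_steps = 4L) {
  stopifnot(inherits(rec, "octqrs_recording"), severity >= 0)
  set.seed(seed)
  n <- nrow(rec$signals)
  fs <- rec$sampling_rate
  out <- rec
  for (ch in seq_len(ncol(rec$signals))) {
    x <- rec$signals[, ch]
    rng <- range(x)
    if (diff(rng) == 0)
      abort("min-max normalization is undefined for a constant channel")
    xn <- 2 * (x - rng[1]) / diff(rng) - 1
    if (severity > 0) {
      t <- (seq_len(n) - 1L) / fs
      art <- numeric(n)
      for (i in seq_len(n_components)) {
        f <- runif(1, 0.1, 1)
        art <- art + runif(1, 0.3, 1) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
      }
      k <- stats::rpois(1, n_steps * n / fs / 60)
      if (k > 0) {
        at <- sample.int(n, k)
        for (s in at) art[s:n] <- art[s:n] + runif(1, -1, 1)
      }
      art <- art / max(abs(art))
      xn <- xn + severity * art
    }
    out$signals[, ch] <- xn
  }
  out
}
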