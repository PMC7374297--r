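# Independent brute-force oracles, written as direct transcriptions of the
# defining formulas with scalar loops. They are deliberately slow and simple
# and share no code with the implementation.

# round-half-up, the convention of printed percentage tables (R's round()
# rounds half to even: round(62.5) == 62)
round_half_up <- function(x) floor(x + 0.5)

# mean of consecutive pairs
oracle_pool_halve <- function(m) {
  out <- matrix(0, nrow(m), ncol(m) / 2)
  for (c in seq_len(nrow(m)))
    for (t in seq_len(ncol(out)))
      out[c, t] <- (m[c, 2 * t - 1] + m[c, 2 * t]) / 2
  out
}

# out[t] = in[t %/% 2] (0-based nearest-neighbour repetition)
oracle_upsample <- function(m) {
  out <- matrix(0, nrow(m), 2 * ncol(m))
  for (c in seq_len(nrow(m)))
    for (t0 in seq_len(2 * ncol(m)) - 1L)
      out[c, t0 + 1] <- m[c, t0 %/% 2 + 1]
  out
}

# direct-summation cross-correlation, stride 1, zero padding that keeps the
# length: pad floor((k-1)/2) left
oracle_conv1d <- function(x, w, bias = NULL) {
  c_out <- dim(w)[1]; c_in <- dim(w)[2]; k <- dim(w)[3]
  T <- ncol(x)
  if (is.null(bias)) bias <- numeric(c_out)
  pl <- floor((k - 1) / 2)
  out <- matrix(0, c_out, T)
  for (o in seq_len(c_out))
    for (t in seq_len(T)) {
      acc <- bias[o]
      for (i in seq_len(c_in))
        for (j in seq_len(k)) {
          src <- t - pl + j - 1
          if (src >= 1 && src <= T) acc <- acc + w[o, i, j] * x[i, src]
        }
      out[o, t] <- acc
    }
  out
}

# octave convolution assembled from the loop-based primitives:
#   Y_H = f(X_H; W_HH) + upsample(f(X_L; W_LH), 2)
#   Y_L = f(X_L; W_LL) + f(pool(X_H, 2); W_HL)
oracle_octconv <- function(x_high, x_low, layer) {
  y_h <- y_l <- NULL
  if (length(layer$b_h)) {
    y_h <- matrix(rep(layer$b_h, ncol(x_high)), length(layer$b_h))
    if (!is.null(x_high)) y_h <- y_h + oracle_conv1d(x_high, layer$W_hh)
    if (!is.null(x_low)) y_h <- y_h + oracle_upsample(oracle_conv1d(x_low, layer$W_lh))
  }
  if (length(layer$b_l)) {
    nl <- if (!is.null(x_low)) ncol(x_low) else ncol(x_high) / 2
    y_l <- matrix(rep(layer$b_l, nl), length(layer$b_l))
    if (!is.null(x_low)) y_l <- y_l + oracle_conv1d(x_low, layer$W_ll)
    if (!is.null(x_high))
      y_l <- y_l + oracle_conv1d(oracle_pool_halve(x_high), layer$W_hl)
  }
  list(high = y_h, low = y_l)
}

# scalar-loop GRU step: r/z gates, candidate with reset-gated state,
# convex combination
oracle_gru_step <- function(x, h, p) {
  H <- length(h); D <- length(x)
  sig <- function(v) 1 / (1 + exp(-v))
  r <- z <- hc <- hn <- numeric(H)
  for (i in seq_len(H)) {
    ar <- p$br[i]; az <- p$bz[i]
    for (d in seq_len(D)) { ar <- ar + p$Wr[i, d] * x[d]; az <- az + p$Wz[i, d] * x[d] }
    for (u in seq_len(H)) { ar <- ar + p$Ur[i, u] * h[u]; az <- az + p$Uz[i, u] * h[u] }
    r[i] <- sig(ar); z[i] <- sig(az)
  }
  for (i in seq_len(H)) {
    a <- p$bh[i]
    for (d in seq_len(D)) a <- a + p$Wh[i, d] * x[d]
    for (u in seq_len(H)) a <- a + p$Uh[i, u] * (r[u] * h[u])
    hc[i] <- tanh(a)
    hn[i] <- (1 - z[i]) * h[i] + z[i] * hc[i]
  }
  hn
}

# scalar double-loop weighted binary cross-entropy:
# (1/M) sum_i sum_j -[beta y log p + (1-y) log(1-p)]
oracle_wbce <- function(p, y, beta, eps = 1e-7) {
  M <- ncol(p)
  tot <- 0
  for (i in seq_len(M))
    for (j in seq_len(nrow(p))) {
      pij <- min(max(p[j, i], eps), 1 - eps)
      tot <- tot - (beta * y[j, i] * log(pij) + (1 - y[j, i]) * log(1 - pij))
    }
  tot / M
}

# loop-based segment mean
oracle_segment_pool <- function(m, frames) {
  flen <- ncol(m) / frames
  out <- matrix(0, nrow(m), frames)
  for (c in seq_len(nrow(m)))
    for (f in seq_len(frames))
      out[c, f] <- mean(m[c, ((f - 1) * flen + 1):(f * flen)])
  out
}

random_layer <- function(k, c_in, c_out, a_in, a_out) {
  ly <- octconv_layer(k, c_in, c_out, a_in, a_out, init = "zeros")
  fill <- function(a) { if (length(a)) a[] <- rnorm(length(a)); a }
  ly$W_hh <- fill(ly$W_hh); ly$W_hl <- fill(ly$W_hl)
  ly$W_lh <- fill(ly$W_lh); ly$W_ll <- fill(ly$W_ll)
  ly$b_h <- fill(ly$b_h); ly$b_l <- fill(ly$b_l)
  ly
}
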