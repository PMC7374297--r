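test_that("average pooling halves length by pairwise means", {
  expect_equal(as.numeric(average_pool_halve(matrix(c(1, 3, 5, 7), 1))), c(2, 6))
  expect_equal(as.numeric(average_pool_halve(matrix(5, 1, 8))), rep(5, 4))
  set.seed(1)
  m <- matrix(rnorm(300), 3, 100)
  expect_equal(average_pool_halve(m), oracle_pool_halve(m), tolerance = 1e-12)
  expect_error(average_pool_halve(matrix(1, 1, 5)), "even")
})

test_that("nearest upsampling doubles length by repetition", {
  expect_equal(as.numeric(upsample_double(matrix(c(2, 6), 1))), c(2, 2, 6, 6))
  const <- matrix(3.5, 2, 10)
  expect_equal(upsample_double(average_pool_halve(const)), const)
  set.seed(2)
  m <- matrix(rnorm(100), 2, 50)
  expect_equal(upsample_double(m), oracle_upsample(m), tolerance = 1e-12)
})

test_that("conv1d matches identity, constant, and brute-force cases", {
  x <- matrix(rnorm(24), 2, 12)
  w_id <- array(0, c(2, 2, 1)); w_id[1, 1, 1] <- 1; w_id[2, 2, 1] <- 1
  expect_equal(conv1d(x, w_id), x)
  w0 <- array(0, c(3, 2, 3))
  expect_equal(conv1d(x, w0, bias = c(1, 2, 3)),
               matrix(rep(c(1, 2, 3), 12), 3))
  set.seed(3)
  w <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  b <- rnorm(2)
  expect_equal(conv1d(x, w, b), oracle_conv1d(x, w, b), tolerance = 1e-10)
  expect_error(conv1d(matrix(0, 3, 10), w), "channels")
})

test_that("even kernels preserve length with asymmetric padding", {
  set.seed(4)
  x <- matrix(rnorm(32), 2, 16)
  for (k in c(2L, 4L, 8L)) {
    w <- array(rnorm(2 * 2 * k), c(2, 2, k))
    y <- conv1d(x, w)
    expect_identical(dim(y), dim(x))
    # oracle uses the same convention: pad floor((k-1)/2) = k/2 - 1 left
    expect_equal(y, oracle_conv1d(x, w), tolerance = 1e-10)
  }
})

test_that("channel split conserves parameters for every alpha", {
  for (a in c(0, 0.25, 0.5, 0.75)) {
    ly <- octconv_layer(5, 8, 16, a, a)
    expect_equal(octconv_n_params(ly, bias = FALSE), 8 * 16 * 5)
    sp <- split_channels(16, a)
    expect_equal(unname(sp["low"]), round(a * 16))
    expect_equal(sum(sp), 16)
  }
  # empty-branch weight groups have zero size
  ly0 <- octconv_layer(3, 4, 4, 0, 0)
  expect_equal(length(ly0$W_lh), 0L)
  expect_equal(length(ly0$b_l), 0L)
})

test_that("octconv at alpha 0 is exactly a vanilla convolution", {
  set.seed(5)
  x <- matrix(rnorm(4 * 16), 4, 16)
  ly <- random_layer(5, 4, 6, 0, 0)
  got <- octconv_forward(freq_map(x, NULL, 0), ly)
  want <- conv1d(x, octconv_as_vanilla(ly), ly$b_h)
  expect_lt(max(abs(got$high - want)), 1e-6)
  expect_null(got$low)
})

test_that("octconv with zero weights yields zero branches", {
  x <- matrix(rnorm(4 * 8), 4, 8)
  ly <- octconv_layer(3, 4, 4, 0, 0.5, init = "zeros")
  out <- octconv_forward(freq_map(x, NULL, 0), ly)
  expect_true(all(out$high == 0))
  expect_true(all(out$low == 0))
  expect_equal(dim(out$low), c(2, 4))
})

test_that("octconv matches the brute-force two-branch oracle", {
  set.seed(6)
  for (rep in 1:25) {
    k <- sample(c(1L, 3L, 5L, 8L), 1)
    c_in <- sample(2:8, 1)
    c_out <- sample(2:8, 1)
    l <- 2L * sample(4:8, 1)
    a_in <- sample(c(0, 0.5), 1)
    a_out <- sample(c(0, 0.5), 1)
    ly <- random_layer(k, c_in, c_out, a_in, a_out)
    si <- split_channels(c_in, a_in)
    x_h <- if (si[1] > 0) matrix(rnorm(si[1] * l), si[1])
    x_l <- if (si[2] > 0) matrix(rnorm(si[2] * l / 2), si[2])
    got <- octconv_forward(freq_map(x_h, x_l, a_in), ly)
    want <- oracle_octconv(x_h, x_l, ly)
    if (!is.null(want$high)) expect_lt(max(abs(got$high - want$high)), 1e-8)
    if (!is.null(want$low)) expect_lt(max(abs(got$low - want$low)), 1e-8)
    # high-branch length is preserved
    if (!is.null(got$high)) expect_equal(ncol(got$high), l)
  }
})

test_that("octconv is linear in its input when bias is zero", {
  set.seed(7)
  ly <- random_layer(3, 4, 4, 0.5, 0.5)
  ly$b_h[] <- 0; ly$b_l[] <- 0
  x_h <- matrix(rnorm(2 * 12), 2); x_l <- matrix(rnorm(2 * 6), 2)
  y1 <- octconv_forward(freq_map(x_h, x_l, 0.5), ly)
  y2 <- octconv_forward(freq_map(3 * x_h, 3 * x_l, 0.5), ly)
  expect_equal(y2$high, 3 * y1$high, tolerance = 1e-10)
  expect_equal(y2$low, 3 * y1$low, tolerance = 1e-10)
})

test_that("octconv rejects mismatched alpha and odd lengths", {
  ly <- octconv_layer(3, 4, 4, 0.5, 0.5)
  x <- freq_map(matrix(0, 4, 8), NULL, 0)
  expect_error(octconv_forward(x, ly), "alpha")
  ly2 <- octconv_layer(3, 4, 4, 0, 0.5)
  x_odd <- freq_map(matrix(0, 4, 7), NULL, 0)
  expect_error(octconv_forward(x_odd, ly2), "even")
})

test_that("freq_map enforces the branch and length invariants", {
  expect_error(freq_map(matrix(0, 2, 8), NULL, 0.5), "low branch")
  expect_error(freq_map(NULL, matrix(0, 2, 4), 0.5), "high branch")
  expect_error(freq_map(matrix(0, 2, 8), matrix(0, 2, 3), 0.5), "length")
  fm <- freq_map(matrix(0, 2, 8), matrix(0, 2, 4), 0.5)
  expect_s3_class(fm, "freq_map")
})

test_that("batched inputs give the same result as per-instance calls", {
  set.seed(8)
  ly <- random_layer(5, 4, 6, 0, 0.5)
  xb <- array(rnorm(4 * 12 * 3), c(4, 12, 3))
  out_b <- octconv_forward(freq_map(xb, NULL, 0), ly)
  for (i in 1:3) {
    out_i <- octconv_forward(freq_map(xb[, , i], NULL, 0), ly)
    expect_equal(out_b$high[, , i], out_i$high, tolerance = 1e-12)
    expect_equal(out_b$low[, , i], out_i$low, tolerance = 1e-12)
  }
})
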