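make_rec <- function(n = 60000L, fqrs = integer(), id = "r1") {
  set.seed(99)
  recording(matrix(rnorm(n * 4), n, 4), fqrs, record_id = id)
}

test_that("recording constructor enforces annotation invariants", {
  expect_error(recording(matrix(0, 100, 4), c(5L, 5L)), "increasing")
  expect_error(recording(matrix(0, 100, 4), c(-1L)), "within")
  expect_error(recording(matrix(0, 100, 4), c(100L)), "within")
  expect_error(recording(matrix(c(NA, rep(0, 399)), 100, 4)), "finite")
})

test_that("windowing yields floor((n - w)/stride) + 1 labeled windows", {
  rec <- make_rec(60000L, c(350L, 400L, 59999L))
  ws <- extract_windows(rec, stride = 1000L)
  expect_equal(dim(ws$x)[3], 60L)
  expect_equal(dim(ws$x)[1:2], c(4L, 1000L))
  # annotation at 350 labels frame 3 (0-based), boundary 400 labels frame 4
  expect_equal(which(ws$y[, 1] == 1L) - 1L, c(3L, 4L))
  expect_equal(which(ws$y[, 60] == 1L) - 1L, 9L)
  # window content matches the raw signal
  expect_equal(ws$x[, , 2], t(rec$signals[1001:2000, ]))
})

test_that("short recordings produce an empty window set with a warning", {
  rec <- make_rec(500L)
  expect_warning(ws <- extract_windows(rec), "shorter")
  expect_equal(dim(ws$x)[3], 0L)
})

test_that("every annotation labels exactly one frame at stride 1000", {
  set.seed(20)
  fqrs <- sort(sample(0:59999, 130))
  rec <- make_rec(60000L, as.integer(fqrs))
  ws <- extract_windows(rec, stride = 1000L)
  # no annotation lost (60000 divides evenly into windows)
  frames_per_ann <- sum(ws$y)
  distinct_frames <- length(unique((fqrs %/% 100)))
  expect_equal(frames_per_ann, distinct_frames)
})

test_that("record split reproduces the published partition", {
  sp <- split_records(sprintf("a%02d", 1:75))
  expect_length(sp$train, 55)
  expect_length(sp$val, 6)
  expect_length(sp$test, 7)
  expect_equal(sp$test, sprintf("a%02d", 1:7))
  expect_equal(sp$val, sprintf("a%02d", 8:13))
  for (ex in c("a33", "a38", "a47", "a52", "a54", "a71", "a74"))
    expect_false(ex %in% unlist(sp))
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0)
  # empty input, unknown ids
  sp0 <- split_records(character())
  expect_equal(lengths(sp0), c(train = 0L, val = 0L, test = 0L))
  expect_error(split_records("b01"), "unknown")
})

test_that("gaussian noise is bounded, seeded, and leaves annotations alone", {
  rec <- make_rec(10000L, c(100L, 5000L))
  n1 <- add_gaussian_noise(rec, level = 3, seed = 4)
  n2 <- add_gaussian_noise(rec, level = 3, seed = 4)
  expect_identical(n1$signals, n2$signals)
  expect_identical(n1$fqrs, rec$fqrs)
  expect_equal(dim(n1$signals), dim(rec$signals))
  # base noise max |.| is 4 uV, so level 3 is bounded by 12
  expect_lte(max(abs(n1$signals - rec$signals)), 3 * 4 + 1e-9)
  # SNR decreases monotonically over increasing levels
  snr <- vapply(c(3, 6, 9), function(lv) {
    noisy <- add_gaussian_noise(rec, lv, seed = 4)
    10 * log10(mean(rec$signals^2) / mean((noisy$signals - rec$signals)^2))
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("motion artifacts are low-frequency, seeded, and label-preserving", {
  rec0 <- generate_recording(synth_config(duration = 30, seed = 21))
  m0 <- add_motion_artifact(rec0, severity = 0, seed = 5)
  # severity 0 returns the min-max normalized signal
  expect_true(all(abs(m0$signals) <= 1 + 1e-12))
  m1 <- add_motion_artifact(rec0, severity = 0.5, seed = 5)
  m2 <- add_motion_artifact(rec0, severity = 0.5, seed = 5)
  expect_identical(m1$signals, m2$signals)
  expect_identical(m1$fqrs, rec0$fqrs)
  # >= 90 % of artifact power below 1 Hz
  art <- m1$signals[, 1] - m0$signals[, 1]
  n <- length(art)
  spec <- Mod(stats::fft(art - mean(art)))^2
  freq <- (seq_len(n) - 1) / n * rec0$sampling_rate
  half <- freq > 0 & freq <= rec0$sampling_rate / 2
  expect_gte(sum(spec[half & freq < 1]) / sum(spec[half]), 0.9)
  # constant channel cannot be normalized
  flat <- recording(matrix(c(rep(0, 100), rnorm(300)), 100, 4))
  expect_error(add_motion_artifact(flat, 0.1), "constant")
})
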