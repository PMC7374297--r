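# Shared fixtures built once per test run.
#
# The scaled-down study: ~2000 one-second synthetic windows (34 recordings
# of 60 s, fetal R amplitude 0.3 of maternal), an alpha = 0.25 reduced
# detector trained for 15 epochs. Built lazily and cached so the training
# cost is paid once; the Grad-CAM localization tests reuse the same fit.

.fixture_env <- new.env(parent = emptyenv())

scaled_down_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  n_rec <- 34L
  recs <- lapply(seq_len(n_rec), function(s)
    generate_recording(synth_config(seed = s, fetal_amplitude_ratio = 0.3)))
  ws <- lapply(recs, extract_windows)
  val_idx <- c(n_rec - 1L, n_rec)
  trn <- bind_windows(ws[-val_idx])
  val <- bind_windows(ws[val_idx])
  net <- build_network(network_config_reduced(alpha = 0.25), seed = 42)
  fit <- train(net, trn, val, train_config(epochs = 15, seed = 42))
  .fixture_env$study <- list(fit = fit, train = trn, val = val,
                             val_recs = recs[val_idx])
  .fixture_env$study
}

# a tiny toy network shared by gradient-flavoured tests
toy_net <- function(alpha = 0.5, seed = 12, ...) {
  cfg <- network_config(in_channels = 2L, window_length = 40L,
                        frames_per_window = 10L, block_filters = c(4L, 6L, 6L),
                        alpha = alpha, gru_hidden = 3L, dropout_rate = 0,
                        normalize = FALSE, ...)
  build_network(cfg, seed = seed)
}
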