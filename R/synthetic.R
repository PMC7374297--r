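#' Synthetic abdominal fetal/maternal ECG
#'
#' A seedable simulator of 4-channel abdominal recordings: a dominant
#' maternal beat train (60-90 bpm), a weaker and faster fetal beat train
#' (110-160 bpm), per-channel linear mixing, and additive Gaussian sensor
#' noise, with the fetal R-peak sample indices kept as ground truth. Beat
#' morphology is a fixed sum of Gaussian bumps standing in for the P, Q, R,
#' S and T waves, which gives the mixture both the sub-1-Hz content of the
#' slow waves and the >10-Hz content of the sharp QRS deflections.
#'
#' @param duration Recording length in seconds.
#' @param sampling_rate Samples per second (the detector assumes 1000).
#' @param maternal_hr,fetal_hr Mean heart rates in beats per minute; drawn
#'   uniformly from the given range when a length-2 vector.
#' @param rr_jitter_cv Coefficient of variation of the multiplicative
#'   Gaussian RR-interval jitter (truncated at +/-20 %).
#' @param maternal_amplitude Maternal R-peak amplitude in microvolts.
#' @param fetal_amplitude_ratio Fetal R amplitude relative to maternal, in
#'   (0, 1]; abdominal leads see the fetus much weaker than the mother.
#' @param channel_gains 4 x 2 mixing matrix (columns: maternal, fetal
#'   gains); `NULL` draws gains uniformly from `[0.5, 1]`.
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise
#'   in microvolts.
#' @param seed Integer seed; the whole recording is a deterministic function
#'   of the configuration including the seed.
#' @return For `synth_config()`, a configuration list of class
#'   `octqrs_synth_config`.
#' @export
synth_config <- function(duration = 60,
                         sampling_rate = 1000L,
                         maternal_hr = c(60, 90),
                         fetal_hr = c(110, 160),
                         rr_jitter_cv = 0.02,
                         maternal_amplitude = 25,
                         fetal_amplitude_ratio = 0.2,
                         channel_gains = NULL,
                         noise_sd = 1,
                         seed = 1L) {
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9)
    abort("duration * sampling_rate must be an integer number of samples")
  stopifnot(all(maternal_hr > 0), all(fetal_hr > 0),
            fetal_amplitude_ratio > 0, fetal_amplitude_ratio <= 1,
            noise_sd >= 0)
  if (!is.null(channel_gains))
    stopifnot(is.matrix(channel_gains), ncol(channel_gains) == 2L)
  structure(list(duration = duration, sampling_rate = as.integer(sampling_rate),
                 maternal_hr = maternal_hr, fetal_hr = fetal_hr,
                 rr_jitter_cv = rr_jitter_cv,
                 maternal_amplitude = maternal_amplitude,
                 fetal_amplitude_ratio = fetal_amplitude_ratio,
                 channel_gains = channel_gains, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "octqrs_synth_config")
}

#' Generate a beat train as strictly increasing R-peak indices
#'
#' RR intervals are `60 / mean_hr` seconds with multiplicative Gaussian
#' jitter of coefficient of variation `jitter_cv`, truncated at +/-20 % of
#' the mean interval.
#'
#' @param mean_hr Mean heart rate in bpm.
#' @param jitter_cv RR jitter coefficient of variation (0 = metronomic).
#' @param duration Duration in seconds.
#' @param sampling_rate Samples per second.
#' @param seed Optional integer seed.
#' @return Integer vector of 0-based R-peak sample indices in
#'   `[0, duration * sampling_rate)`.
#' @export
generate_beat_train <- function(mean_hr, jitter_cv = 0.02, duration = 60,
                                sampling_rate = 1000L, seed = NULL) {
  stopifnot(mean_hr > 0, jitter_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_samples <- round(duration * sampling_rate)
  mean_rr <- 60 / mean_hr * sampling_rate
  n_max <- ceiling(n_samples / (mean_rr * 0.8)) + 2L
  mult <- 1 + rnorm(n_max) * jitter_cv
  mult <- pmin(pmax(mult, 0.8), 1.2)
  # first beat lands within one mean interval of the start
  t0 <- runif(1) * mean_rr
  times <- cumsum(c(t0, mean_rr * mult))
  peaks <- as.integer(round(times[times < n_samples]))
  peaks <- peaks[peaks >= 0L & peaks < n_samples]
  unique(peaks)
}

# Gaussian-bump morphology: offsets (ms), widths (ms) and amplitudes
# relative to the R wave. Plausible adult shape; the fetal template is the
# same shape compressed in time.
ecg_morphology <- function(scale = 1) {
  list(offset_ms = c(P = -160, Q = -25, R = 0, S = 25, T = 220) * scale,
       width_ms = c(P = 35, Q = 8, R = 9, S = 9, T = 60) * scale,
       rel_amp = c(P = 0.12, Q = -0.18, R = 1, S = -0.25, T = 0.32))
}

#' Render an ECG-like signal from R-peak locations
#'
#' Each beat contributes five Gaussian bumps (P, Q, R, S, T) at fixed
#' offsets and widths, scaled so that the rendered value at each R-peak
#' index equals `amplitude` up to the small overlap of neighbouring bumps.
#' Beats closer than the template support simply sum.
#'
#' @param peaks Strictly increasing 0-based R-peak sample indices.
#' @param n_samples Output signal length.
#' @param amplitude R-peak amplitude (microvolts).
#' @param morphology A list as returned by `ecg_morphology()`.
#' @param sampling_rate Samples per second.
#' @return Numeric vector of length `n_samples`.
#' @export
render_ecg <- function(peaks, n_samples, amplitude = 1,
                       morphology = ecg_morphology(), sampling_rate = 1000L) {
  if (length(peaks) > 1 && any(diff(peaks) <= 0))
    abort("peaks must be strictly increasing")
  sig <- numeric(n_samples)
  if (length(peaks) == 0L) return(sig)
  ms <- sampling_rate / 1000
  for (w in seq_along(morphology$offset_ms)) {
    centre <- peaks + morphology$offset_ms[w] * ms
    width <- morphology$width_ms[w] * ms
    half <- ceiling(4 * width)
    for (c0 in centre) {
      lo <- max(0, floor(c0 - half))
      hi <- min(n_samples - 1, ceiling(c0 + half))
      if (hi < lo) next  # bump support falls outside the signal
      idx <- lo:hi
      sig[idx + 1] <- sig[idx + 1] +
        morphology$rel_amp[w] * exp(-0.5 * ((idx - c0) / width)^2)
    }
  }
  sig * amplitude
}

#' Generate a synthetic abdominal recording
#'
#' Channel `i` is `g_m[i] * maternal + g_f[i] * ratio * fetal + noise`,
#' where the maternal and fetal components are rendered beat trains with
#' independent rhythms and the noise is white Gaussian with standard
#' deviation `noise_sd`. The returned [recording()] carries the fetal
#' R-peak indices as its ground-truth annotations.
#'
#' @param config A [synth_config()].
#' @return A [recording()] with a `synth` attribute holding the drawn heart
#'   rates, gains and the maternal R-peak indices.
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "octqrs_synth_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  pick <- function(rng) if (length(rng) == 2L) runif(1, rng[1], rng[2]) else rng[1]
  m_hr <- pick(config$maternal_hr)
  f_hr <- pick(config$fetal_hr)
  m_peaks <- generate_beat_train(m_hr, config$rr_jitter_cv, config$duration, fs)
  f_peaks <- generate_beat_train(f_hr, config$rr_jitter_cv, config$duration, fs)
  # fetal QRS is narrower and earlier: compress the template in time
  m_sig <- render_ecg(m_peaks, n, config$maternal_amplitude, ecg_morphology(1), fs)
  f_sig <- render_ecg(f_peaks, n, config$maternal_amplitude * config$fetal_amplitude_ratio,
                      ecg_morphology(0.6), fs)
  gains <- config$channel_gains
  if (is.null(gains)) gains <- matrix(runif(8, 0.5, 1), nrow = 4, ncol = 2)
  signals <- matrix(0, n, 4)
  for (i in 1:4) {
    signals[, i] <- gains[i, 1] * m_sig + gains[i, 2] * f_sig
    if (config$noise_sd > 0)
      signals[, i] <- signals[, i] + rnorm(n, sd = config$noise_sd)
  }
  rec <- recording(signals, f_peaks,
                   record_id = sprintf("synth%03d", config$seed %% 1000L),
                   sampling_rate = fs)
  attr(rec, "synth") <- list(maternal_hr = m_hr, fetal_hr = f_hr,
                             gains = gains, maternal_peaks = m_peaks,
                             config = config)
  rec
}
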