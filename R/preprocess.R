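#' Butterworth high-pass filter
#'
#' Fifth-order (by default) Butterworth high-pass with 30 Hz cut-off,
#' applied forward-backward by default (zero phase, so cardiac state
#' boundaries are not delayed relative to ground truth). With
#' `zero_phase = FALSE` a single causal pass is used, whose magnitude
#' response at frequency f is the analytic
#' `1 / sqrt(1 + (fc / f)^(2 * order))`.
#'
#' @param x Numeric sample vector.
#' @param fs_hz Sampling rate in Hz.
#' @param order Filter order (default 5).
#' @param fc_hz Cut-off frequency in Hz (default 30).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return Filtered vector of the same length.
#' @export
highpass_filter <- function(x, fs_hz, order = 5L, fc_hz = 30,
                            zero_phase = TRUE) {
  if (fc_hz >= fs_hz / 2) stop("cut-off must be below the Nyquist frequency")
  if (length(x) <= 3 * order) stop("signal too short for the filter order")
  bt <- signal::butter(order, fc_hz / (fs_hz / 2), type = "high")
  if (zero_phase) zero_phase_filter(bt$b, bt$a, x)
  else single_pass_filter(bt$b, bt$a, x)
}

#' Mains notch filter
#'
#' Second-order IIR notch (biquad, Q = 30 by default) at `f0_hz`, applied
#' forward-backward. Attenuates a pure 50 Hz tone by well over 30 dB while
#' changing 40 and 60 Hz components by less than 1 dB.
#'
#' @param x Numeric sample vector.
#' @param fs_hz Sampling rate in Hz.
#' @param f0_hz Notch frequency in Hz (default 50).
#' @param Q Quality factor (default 30).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(x, fs_hz, f0_hz = 50, Q = 30, zero_phase = TRUE) {
  if (f0_hz >= fs_hz / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * f0_hz / fs_hz
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  if (zero_phase) zero_phase_filter(b, a, x)
  else single_pass_filter(b, a, x)
}

#' Filter a whole multi-channel recording
#'
#' Applies the high-pass and notch filters channel by channel to the full
#' recording (filtering precedes cropping).
#'
#' @param rec A [pcg_recording()].
#' @param hp_hz High-pass cut-off (default 30 Hz).
#' @param notch_hz Notch frequency (default 50 Hz).
#' @return The filtered [pcg_recording()].
#' @export
preprocess_recording <- function(rec, hp_hz = 30, notch_hz = 50) {
  y <- rec$samples
  for (c in seq_len(nrow(y))) {
    y[c, ] <- highpass_filter(y[c, ], rec$fs_hz, fc_hz = hp_hz)
    y[c, ] <- notch_filter(y[c, ], rec$fs_hz, f0_hz = notch_hz)
  }
  pcg_recording(y, rec$fs_hz, rec$subject_id, rec$label)
}

#' Crop a recording into fixed-length segments
#'
#' Splits the recording into consecutive non-overlapping segments of
#' `seg_len_s` seconds (default 10 s, so a 5-minute recording yields 30
#' segments); a trailing remainder shorter than one segment is discarded.
#'
#' @param rec A [pcg_recording()].
#' @param seg_len_s Segment length in seconds.
#' @return A list of [pcg_segment()] objects.
#' @export
crop_segments <- function(rec, seg_len_s = 10) {
  M <- round(seg_len_s * rec$fs_hz)
  N <- ncol(rec$samples)
  if (N < M) stop("recording shorter than one segment")
  n_seg <- N %/% M
  lapply(seq_len(n_seg) - 1L, function(i) {
    pcg_segment(rec$samples[, (i * M + 1):((i + 1) * M), drop = FALSE],
                rec$fs_hz, rec$subject_id, rec$label,
                segment_index = i, offset = i * M)
  })
}

#' Default segment quality thresholds
#'
#' @param max_clip_frac Maximum tolerated fraction of near-rail samples.
#' @param max_spectral_flatness Maximum tolerated spectral flatness
#'   (white noise approaches 1; structured heart sound is far lower).
#' @param min_env_autocorr Minimum envelope autocorrelation peak in the
#'   0.4-1.5 s lag band (cardiac periodicity evidence).
#' @return A named list of thresholds.
#' @export
quality_thresholds <- function(max_clip_frac = 0.01,
                               max_spectral_flatness = 0.5,
                               min_env_autocorr = 0.15) {
  list(max_clip_frac = max_clip_frac,
       max_spectral_flatness = max_spectral_flatness,
       min_env_autocorr = min_env_autocorr)
}

#' Segment quality gate
#'
#' Deterministic per-channel quality metrics with a pass/fail verdict:
#' a segment fails if any channel exceeds the configured thresholds.
#' Metrics: `clip_frac`, the fraction of samples within 1% of the channel's
#' absolute maximum; `spectral_flatness`, the geometric/arithmetic mean
#' ratio of the periodogram; `env_autocorr`, the maximum autocorrelation of
#' the 50 Hz amplitude envelope over lags 0.4-1.5 s.
#'
#' @param seg A [pcg_segment()].
#' @param thresholds A [quality_thresholds()] list.
#' @return A list with `pass` (logical) and `metrics` (data.frame with one
#'   row per channel).
#' @export
assess_quality <- function(seg, thresholds = quality_thresholds()) {
  fs <- seg$fs_hz
  rows <- lapply(seq_len(nrow(seg$samples)), function(c) {
    x <- seg$samples[c, ]
    rail <- max(abs(x))
    clip <- if (rail > 0) mean(abs(x) >= 0.99 * rail) else 1
    pg <- Mod(stats::fft(x - mean(x)))^2
    pg <- pg[2:(length(pg) %/% 2)]
    pg <- pmax(pg, .Machine$double.xmin)
    flat <- exp(mean(log(pg))) / mean(pg)
    # amplitude envelope at 50 Hz
    dec <- max(1L, round(fs / 50))
    env <- abs(x)
    env <- as.numeric(stats::filter(env, rep(1 / dec, dec), sides = 2))
    env <- env[seq(dec %/% 2 + 1, length(env) - dec, by = dec)]
    env <- env - mean(env, na.rm = TRUE)
    env[is.na(env)] <- 0
    ac <- stats::acf(env, lag.max = ceiling(1.5 * 50), plot = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1
    band <- lags >= 0.4 * 50 & lags <= 1.5 * 50
    env_ac <- if (any(band)) max(ac[band]) else 0
    data.frame(channel = c, clip_frac = clip, spectral_flatness = flat,
               env_autocorr = env_ac)
  })
  metrics <- do.call(rbind, rows)
  pass <- all(metrics$clip_frac <= thresholds$max_clip_frac) &&
    all(metrics$spectral_flatness <= thresholds$max_spectral_flatness) &&
    all(metrics$env_autocorr >= thresholds$min_env_autocorr)
  list(pass = pass, metrics = metrics)
}

#' Normalize a signal to zero mean and unit SD
#'
#' @param x Numeric vector with positive SD.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
normalize_signal <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("cannot normalize a constant signal")
  (x - mean(x)) / s
}
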