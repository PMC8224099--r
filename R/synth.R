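#' Subject profile for the synthetic PCG generator
#'
#' Describes one synthetic subject: label, heart rate and its cycle-length
#' jitter, the strength of the disease signature (murmur level and
#' inter-channel dyssynchrony) and per-channel sensor gains. The seed fully
#' determines the subject's recording.
#'
#' @param subject_id Subject identifier string.
#' @param label `"CAD"` or `"non-CAD"`.
#' @param heart_rate_bpm Heart rate in beats per minute, in `[40, 140]`.
#' @param hr_jitter SD of the cycle-length noise as a fraction of the mean
#'   cycle (i.i.d. Gaussian, truncated at 3 SD).
#' @param murmur_snr_db Murmur power relative to the high-passed (30 Hz)
#'   in-window signal power, in dB (`-Inf` disables the murmur). Only
#'   used for CAD subjects.
#' @param desync_level Inter-channel dyssynchrony in `[0, 1]`; 0 means the
#'   channels stay fully coupled. Only used for CAD subjects.
#' @param channel_gains Five positive per-channel gains.
#' @param hf_noise_db Benign broadband (150-600 Hz) noise floor relative to
#'   the baseline rumble power, in dB; present for every subject so that
#'   high-frequency features have non-degenerate variance in both groups
#'   while staying small against a murmur.
#' @param sensor_noise SD of the channel-independent baseline noise (same
#'   scale as the unit S1 burst); subject-level variation in this benign
#'   decoupling gives cross-entropy features non-degenerate variance in
#'   the non-CAD group.
#' @param seed Integer seed; bit-identical samples for identical profiles.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S1",
                            label = c("non-CAD", "CAD"),
                            heart_rate_bpm = 75,
                            hr_jitter = 0.03,
                            murmur_snr_db = -Inf,
                            desync_level = 0,
                            channel_gains = c(1, 1.1, 1.05, 0.9, 0.95),
                            hf_noise_db = -6,
                            sensor_noise = 0.01,
                            seed = 1L) {
  label <- match.arg(label)
  if (heart_rate_bpm < 40 || heart_rate_bpm > 140)
    stop("heart_rate_bpm must be in [40, 140]")
  if (hr_jitter < 0) stop("hr_jitter must be nonnegative")
  if (length(channel_gains) != 5 || any(channel_gains <= 0))
    stop("channel_gains must be 5 positive values")
  if (desync_level < 0 || desync_level > 1)
    stop("desync_level must be in [0, 1]")
  structure(list(subject_id = subject_id, label = label,
                 heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
                 murmur_snr_db = murmur_snr_db, desync_level = desync_level,
                 channel_gains = channel_gains, hf_noise_db = hf_noise_db,
                 sensor_noise = sensor_noise, seed = as.integer(seed)),
            class = "subject_profile")
}

# fixed state fractions of the cardiac cycle; chosen so duration-ratio
# features are scale-free and systole/CC sits at a physiological 0.35
STATE_FRAC <- c(s1 = 0.09, sys = 0.35, s2 = 0.07)

# Gaussian-enveloped multi-sine wavelet centred at 0 over times t (seconds)
burst_wave <- function(t, dur, freqs, weights, phases) {
  env <- exp(-0.5 * (t / (dur / 5))^2)
  s <- 0
  for (k in seq_along(freqs))
    s <- s + weights[k] * sin(2 * pi * freqs[k] * t + phases[k])
  env * s
}

# economy pink-noise shaping filter (3-pole approximation) applied to
# standard white noise
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  as.numeric(signal::filter(b, a, w)) / 0.0077  # rescale to ~unit SD
}

# cardiac baseline rumble: pink noise rolled off above ~80 Hz, so that the
# clean diastolic spectrum carries essentially no energy above 200 Hz
baseline_noise <- function(n, fs) {
  bt <- signal::butter(2, 80 / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bt, pink_noise(n)))
}

bandlimited_noise <- function(n, fs, lo, hi) {
  bt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bt, stats::rnorm(n)))
  x / stats::sd(x)
}

#' Generate one five-channel PCG recording with ground truth
#'
#' Synthesizes quasi-periodic cardiac cycles made of Gaussian-enveloped S1
#' (30-100 Hz) and S2 (50-150 Hz) wavelets separated by near-silent
#' systolic/diastolic baselines, on top of pink noise, a 0.2 Hz
#' respiration drift, 50 Hz mains interference and a benign broadband
#' noise floor. The five channels are gain-scaled, time-aligned copies
#' with channel-specific morphology perturbations (small frequency and
#' phase offsets). The returned annotation describes the generated cycles
#' exactly, as 0-based half-open sample indices.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Recording duration in seconds (default 300, i.e. the
#'   5-minute protocol). Must cover at least 3 cardiac cycles.
#' @param fs_hz Sampling rate in Hz (default 2000).
#' @param mains_amp Amplitude of the 50 Hz mains component (default 0.05,
#'   relative to a unit S1 burst).
#' @param drift_amp Amplitude of the 0.2 Hz respiration drift (default 0.3).
#' @return A list with elements `recording` (a [pcg_recording()]) and
#'   `states` (a [cycle_annotation()] with source `"ground_truth"`).
#' @export
generate_recording <- function(profile, duration_s = 300, fs_hz = 2000,
                               mains_amp = 0.05, drift_amp = 0.3) {
  stopifnot(inherits(profile, "subject_profile"))
  cc_mean <- 60 / profile$heart_rate_bpm
  if (duration_s < 3 * cc_mean)
    stop(sprintf("duration_s must cover at least 3 cardiac cycles (>= %.2f s)",
                 3 * cc_mean))
  N <- round(duration_s * fs_hz)
  with_seed(profile$seed, {
    # cycle lengths with truncated Gaussian jitter
    n_max <- ceiling(duration_s / cc_mean * 1.5) + 2
    eps <- stats::rnorm(n_max, 0, 1)
    eps <- pmin(pmax(eps, -3), 3) * profile$hr_jitter
    lens <- cc_mean * (1 + eps)
    starts <- cumsum(c(0, lens))
    keep <- which(starts[-1] <= duration_s + 1e-9)
    n_cy <- length(keep)
    # channel morphology perturbations (per subject, deterministic)
    f1 <- c(35, 60, 90);  w1 <- c(1, 0.7, 0.4)
    f2 <- c(60, 100, 140); w2 <- c(1, 0.7, 0.5)
    ch_ffac <- 1 + stats::rnorm(5, 0, 0.03)
    ch_ph1 <- matrix(stats::runif(15, 0, 2 * pi), nrow = 5)
    ch_ph2 <- matrix(stats::runif(15, 0, 2 * pi), nrow = 5)
    amp1 <- 1 + pmin(pmax(stats::rnorm(n_cy, 0, 0.05), -0.15), 0.15)
    amp2 <- 0.8 * (1 + pmin(pmax(stats::rnorm(n_cy, 0, 0.05), -0.15), 0.15))

    x <- matrix(0, nrow = 5, ncol = N)
    ann <- matrix(0L, nrow = n_cy, ncol = 5)
    colnames(ann) <- c("s1_start", "s1_end", "sys_end", "s2_end", "dia_end")
    for (k in seq_len(n_cy)) {
      t0 <- starts[k]; L <- lens[k]
      b <- round(c(t0, t0 + STATE_FRAC["s1"] * L,
                   t0 + sum(STATE_FRAC[c("s1", "sys")]) * L,
                   t0 + sum(STATE_FRAC) * L,
                   t0 + L) * fs_hz)
      ann[k, ] <- as.integer(b)
      # S1 burst centred mid-S1, S2 centred mid-S2
      for (bi in 1:2) {
        if (bi == 1) {
          ctr <- (b[1] + b[2]) / 2 / fs_hz; dur <- STATE_FRAC["s1"] * L
          fr <- f1; wt <- w1 * amp1[k]; ph <- ch_ph1
        } else {
          ctr <- (b[3] + b[4]) / 2 / fs_hz; dur <- STATE_FRAC["s2"] * L
          fr <- f2; wt <- w2 * amp2[k]; ph <- ch_ph2
        }
        half <- ceiling(dur * fs_hz / 2)
        i0 <- max(1, round(ctr * fs_hz) - half)
        i1 <- min(N, round(ctr * fs_hz) + half)
        tt <- (i0:i1) / fs_hz - ctr
        for (c in 1:5)
          x[c, i0:i1] <- x[c, i0:i1] +
            burst_wave(tt, dur, fr * ch_ffac[c], wt, ph[c, ])
      }
    }
    # shared baseline rumble, per-channel sensor noise, drift, mains, and
    # the benign broadband noise floor (150-600 Hz) whose level is
    # hf_noise_db relative to the baseline rumble power
    shared_base <- 0.02 * baseline_noise(N, fs_hz)
    drift <- drift_amp * sin(2 * pi * 0.2 * (1:N) / fs_hz)
    mains_ph <- stats::runif(5, 0, 2 * pi)
    base_sd <- sqrt(0.02^2 + 0.01^2)
    hf_sd <- base_sd * 10^(profile$hf_noise_db / 20)
    for (c in 1:5) {
      chn <- profile$sensor_noise * baseline_noise(N, fs_hz) +
        hf_sd * bandlimited_noise(N, fs_hz, 150, 600)
      mains <- mains_amp * sin(2 * pi * 50 * (1:N) / fs_hz + mains_ph[c])
      x[c, ] <- profile$channel_gains[c] *
        (x[c, ] + shared_base + chn + drift + mains)
    }
    rec <- pcg_recording(x, fs_hz, profile$subject_id, profile$label)
    states <- cycle_annotation(as.data.frame(ann), source = "ground_truth")
    list(recording = rec, states = states)
  })
}

#' Inject the CAD signature into a recording
#'
#' Adds band-limited (200-800 Hz) murmur noise during the systolic and
#' diastolic windows at `murmur_snr_db` relative to the per-channel
#' high-passed signal power in those windows (scaled further by a
#' lognormal per-channel site-audibility gain), and degrades
#' inter-channel coupling in
#' proportion to `desync_level`: the murmur is a mixture of a shared and a
#' channel-independent component (weights `sqrt(1 - d)` / `sqrt(d)`), the
#' shared component is phase-jittered per channel, and channel-independent
#' low-frequency (30-200 Hz) noise is mixed in. Pairwise cross entropy
#' (XSampEn/XFuzzyEn/JDistEn) therefore increases with `desync_level`.
#' With `desync_level = 0` and `murmur_snr_db = -Inf` the recording is
#' returned unchanged.
#'
#' @param rec A [pcg_recording()].
#' @param states The matching ground-truth [cycle_annotation()].
#' @param profile The CAD [subject_profile()] that generated `rec`.
#' @return A [pcg_recording()] with the signature added.
#' @export
inject_cad_signature <- function(rec, states, profile) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(profile, "subject_profile"))
  if (profile$label != "CAD")
    stop("inject_cad_signature requires a CAD profile")
  d <- profile$desync_level
  snr <- profile$murmur_snr_db
  if (d == 0 && identical(snr, -Inf)) return(rec)
  fs <- rec$fs_hz
  N <- ncol(rec$samples)
  cy <- states$cycles
  mask <- rep(FALSE, N)
  for (k in seq_len(nrow(cy))) {
    mask[(cy$s1_end[k] + 1):cy$sys_end[k]] <- TRUE   # systole
    mask[(cy$s2_end[k] + 1):cy$dia_end[k]] <- TRUE   # diastole
  }
  x <- rec$samples
  with_seed(profile$seed + 104729L, {
    if (is.finite(snr)) {
      shared <- bandlimited_noise(N, fs, 200, 800)
      # site-dependent murmur audibility: the murmur reaches each
      # auscultation location with its own lognormal gain
      site_gain <- exp(stats::rnorm(5, 0, 1.2))
      for (c in 1:5) {
        indep <- if (d > 0) bandlimited_noise(N, fs, 200, 800) else 0
        jit <- if (d > 0) round(stats::runif(1, -1, 1) * d * 0.05 * fs) else 0
        sh <- if (jit != 0) shared[((seq_len(N) - 1 + jit) %% N) + 1] else shared
        mur <- sqrt(1 - d) * sh + sqrt(d) * indep
        # reference power: the cardiac baseline in the murmur windows,
        # i.e. the in-window power after removing drift/mains-scale trends
        ref <- highpass_filter(x[c, ], fs, fc_hz = 30)
        pw <- mean(ref[mask]^2)
        x[c, mask] <- x[c, mask] +
          site_gain[c] * sqrt(pw * 10^(snr / 10)) * mur[mask]
      }
    }
    if (d > 0) {
      for (c in 1:5) {
        lf <- bandlimited_noise(N, fs, 30, 200)
        ref <- highpass_filter(rec$samples[c, ], fs, fc_hz = 30)
        x[c, ] <- x[c, ] + d * 0.2 * sqrt(mean(ref^2)) * lf
      }
    }
  })
  pcg_recording(x, fs, rec$subject_id, rec$label)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject physiology and disease-signature parameters from the
#' cohort distributions (heart rate ~ N(75, 10) bpm clipped to `[55, 110]`,
#' cycle jitter ~ U(0.02, 0.06), lognormal per-channel gain and sensor
#' noise variation, benign noise floor ~ N(-5, 3) dB; for CAD subjects
#' murmur SNR ~ N(-9, 4) dB and dyssynchrony ~ U(0.15, 0.7)), generates
#' each recording
#' and injects the CAD signature for CAD subjects. Per-subject seeds are
#' derived deterministically from the master seed.
#'
#' @param n_cad,n_noncad Number of subjects per group (default 21 / 15).
#' @param seed Master seed.
#' @param duration_s Per-subject recording duration in seconds.
#' @param fs_hz Sampling rate.
#' @return A list with one element per subject, each a list with
#'   `profile`, `recording`, `states`.
#' @export
generate_cohort <- function(n_cad = 21L, n_noncad = 15L, seed = 1L,
                            duration_s = 300, fs_hz = 2000) {
  if (n_cad < 0 || n_noncad < 0) stop("subject counts must be nonnegative")
  n <- n_cad + n_noncad
  if (n == 0) return(list())
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    labels <- c(rep("CAD", n_cad), rep("non-CAD", n_noncad))
    profiles <- lapply(seq_len(n), function(i) {
      subject_profile(
        subject_id = sprintf("%s%02d", ifelse(labels[i] == "CAD", "C", "N"), i),
        label = labels[i],
        heart_rate_bpm = min(110, max(55, stats::rnorm(1, 75, 10))),
        hr_jitter = stats::runif(1, 0.02, 0.06),
        murmur_snr_db = if (labels[i] == "CAD") stats::rnorm(1, -12, 4) else -Inf,
        desync_level = if (labels[i] == "CAD") stats::runif(1, 0.15, 0.7) else 0,
        channel_gains = c(1, 1.1, 1.05, 0.9, 0.95) * exp(stats::rnorm(5, 0, 0.2)),
        hf_noise_db = stats::rnorm(1, -4, 3),
        sensor_noise = 0.01 * exp(stats::rnorm(1, 0, 0.6)),
        seed = sub_seeds[i])
    })
    lapply(profiles, function(pf) {
      g <- generate_recording(pf, duration_s = duration_s, fs_hz = fs_hz)
      if (pf$label == "CAD")
        g$recording <- inject_cad_signature(g$recording, g$states, pf)
      list(profile = pf, recording = g$recording, states = g$states)
    })
  })
}
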