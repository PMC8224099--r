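time_feature_basenames <- function() {
  c("CC", "IntS1", "IntS2", "IntSys", "IntDia",
    "Ratio_SysCC", "Ratio_DiaCC", "Ratio_SysDia",
    "Amp_SysS1", "Amp_DiaS2")
}

freq_feature_basenames <- function() {
  c("HFAll_S1", "LFAll_S1", "HFAll_S2", "LFAll_S2",
    "HFAll_Sys", "LFAll_Sys", "HFAll_Dia", "LFAll_Dia")
}

mean_sd_block <- function(per_cycle_mat, basenames) {
  out <- numeric(0)
  for (q in seq_along(basenames)) {
    v <- per_cycle_mat[q, ]
    out[paste0("m_", basenames[q])] <- mean(v)
    out[paste0("sd_", basenames[q])] <- pop_sd(v)
  }
  out
}

#' Time-domain feature block (20 features)
#'
#' Per cardiac cycle, computes the durations (in seconds) of the cycle,
#' S1, S2, systole and diastole, the duration ratios systole/cycle,
#' diastole/cycle and systole/diastole, and the average-amplitude ratios
#' systole/S1 and diastole/S2 (amplitude = mean absolute value over the
#' state window). Each of the 10 quantities is summarized by its mean and
#' population SD across cycles: 20 features. Durations and ratios are
#' invariant to channel gain.
#'
#' @param seg_channel Numeric vector: one channel of a segment.
#' @param ann A [cycle_annotation()] for that channel.
#' @param fs_hz Sampling rate in Hz.
#' @return Named numeric vector of length 20 (`m_CC`, `sd_CC`, ...,
#'   `sd_Amp_DiaS2`).
#' @export
time_domain_features <- function(seg_channel, ann, fs_hz) {
  if (n_cycles(ann) < 3) stop("at least 3 cycles are required")
  cy <- ann$cycles
  sl <- state_slices(seg_channel, ann)
  per <- vapply(seq_len(nrow(cy)), function(k) {
    r <- cy[k, ]
    cc <- (r$dia_end - r$s1_start) / fs_hz
    s1 <- (r$s1_end - r$s1_start) / fs_hz
    s2 <- (r$s2_end - r$sys_end) / fs_hz
    sys <- (r$sys_end - r$s1_end) / fs_hz
    dia <- (r$dia_end - r$s2_end) / fs_hz
    a_s1 <- mean(abs(sl[[k]]$s1))
    a_s2 <- mean(abs(sl[[k]]$s2))
    a_sys <- mean(abs(sl[[k]]$systole))
    a_dia <- mean(abs(sl[[k]]$diastole))
    c(cc, s1, s2, sys, dia, sys / cc, dia / cc, sys / dia,
      a_sys / a_s1, a_dia / a_s2)
  }, numeric(10))
  mean_sd_block(per, time_feature_basenames())
}

#' High/low-frequency power proportions of one state slice
#'
#' Power spectrum via the discrete Fourier transform; the high-frequency
#' proportion is the power above 200 Hz divided by the total power from 0
#' to Nyquist, the low-frequency proportion the power below 50 Hz divided
#' by the total. Both lie in `[0, 1]` and are invariant to amplitude
#' scaling.
#'
#' @param state_slice Numeric vector (one state window), length >= 16.
#' @param fs_hz Sampling rate in Hz.
#' @param hf_cut,lf_cut Band thresholds in Hz (defaults 200 and 50).
#' @return Named numeric vector `c(hf_prop, lf_prop)`.
#' @export
state_spectrum_proportions <- function(state_slice, fs_hz,
                                       hf_cut = 200, lf_cut = 50) {
  n <- length(state_slice)
  if (n < 16) stop("state slice too short for a spectrum")
  p <- Mod(stats::fft(state_slice))^2
  half <- seq_len(n %/% 2 + 1)
  p <- p[half]
  f <- (half - 1) * fs_hz / n
  tot <- sum(p)
  if (tot <= 0) return(c(hf_prop = 0, lf_prop = 0))
  c(hf_prop = sum(p[f > hf_cut]) / tot, lf_prop = sum(p[f < lf_cut]) / tot)
}

#' Frequency-domain feature block (16 features)
#'
#' Per cycle, computes the high- and low-frequency power proportions of
#' each of the four state slices (S1, S2, systole, diastole) and
#' summarizes each of the 8 quantities by its mean and population SD
#' across cycles: 16 features.
#'
#' @inheritParams time_domain_features
#' @return Named numeric vector of length 16 (`m_HFAll_S1`, ...,
#'   `sd_LFAll_Dia`).
#' @export
frequency_domain_features <- function(seg_channel, ann, fs_hz) {
  if (n_cycles(ann) < 3) stop("at least 3 cycles are required")
  sl <- state_slices(seg_channel, ann)
  per <- vapply(sl, function(cyc) {
    out <- numeric(8)
    states <- list(cyc$s1, cyc$s2, cyc$systole, cyc$diastole)
    for (s in 1:4) {
      pr <- state_spectrum_proportions(states[[s]], fs_hz)
      out[2 * s - 1] <- pr["hf_prop"]
      out[2 * s] <- pr["lf_prop"]
    }
    out
  }, numeric(8))
  mean_sd_block(per, freq_feature_basenames())
}
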