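#' Shannon energy envelope
#'
#' Normalizes the signal to unit maximum amplitude, computes the Shannon
#' energy `-x^2 * log(x^2)` sample-wise, smooths it with a 20 ms moving
#' average and downsamples the result to 50 Hz. The envelope is
#' nonnegative and insensitive to overall gain.
#'
#' @param x Numeric sample vector.
#' @param fs_hz Sampling rate of `x` in Hz.
#' @return A list with `envelope` (numeric vector) and `fs_env` (50).
#' @export
shannon_energy_envelope <- function(x, fs_hz) {
  if (length(x) == 0) stop("empty input")
  mx <- max(abs(x))
  xn <- if (mx > 0) x / mx else x
  e <- xn^2
  se <- ifelse(e > 0, -e * log(e), 0)
  w <- max(1L, round(0.02 * fs_hz))
  sm <- as.numeric(stats::filter(se, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  dec <- max(1L, round(fs_hz / 50))
  env <- sm[seq(dec %/% 2 + 1L, length(sm), by = dec)]
  list(envelope = pmax(env, 0), fs_env = fs_hz / dec)
}

# local maxima above a relative threshold, greedily separated by min_dist
pick_peaks <- function(env, min_dist, rel_thresh = 0.2) {
  n <- length(env)
  if (n < 3) return(integer(0))
  thr <- rel_thresh * max(env)
  cand <- which(env[2:(n - 1)] >= env[1:(n - 2)] &
                  env[2:(n - 1)] > env[3:n] &
                  env[2:(n - 1)] > thr) + 1L
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand)
    if (all(abs(keep - p) >= min_dist)) keep <- c(keep, p)
  sort(keep)
}

#' Delimit cardiac states within a segment
#'
#' With ground truth supplied, returns the generator's annotation cropped
#' to the segment window (indices shifted to segment coordinates;
#' incomplete boundary cycles dropped). Otherwise peaks of the Shannon
#' energy envelope are picked and assigned alternately to S1 and S2 using
#' the physiological rule that diastole (S2 to next S1) is longer than
#' systole (S1 to S2); when the two assignments are nearly tied the one
#' minimizing the variance of the systolic intervals wins. Fixed-width
#' state windows (S1: peak +/- 45 ms, S2: peak +/- 35 ms) delimit the four
#' states.
#'
#' A segment in which fewer than 3 complete cycles are found is flagged
#' unusable by returning an annotation with zero cycles; downstream
#' feature extraction skips such segments.
#'
#' @param seg A [pcg_segment()].
#' @param channel Channel used for envelope segmentation (default 2).
#' @param truth Optional ground-truth [cycle_annotation()] in recording
#'   coordinates.
#' @return A [cycle_annotation()] in segment coordinates.
#' @export
segment_states <- function(seg, channel = 2L, truth = NULL) {
  M <- ncol(seg$samples)
  if (!is.null(truth)) {
    cy <- truth$cycles
    keep <- cy$s1_start >= seg$offset & cy$dia_end <= seg$offset + M
    cy <- cy[keep, , drop = FALSE]
    cy[] <- lapply(cy, function(v) as.integer(v - seg$offset))
    rownames(cy) <- NULL
    return(cycle_annotation(cy, source = "ground_truth"))
  }
  fs <- seg$fs_hz
  x <- normalize_signal(seg$samples[channel, ])
  ev <- shannon_energy_envelope(x, fs)
  fse <- ev$fs_env
  # extra smoothing (~70 ms) merges multi-lobed burst envelopes into one
  # peak per heart sound before picking
  env <- as.numeric(stats::filter(ev$envelope, rep(1 / 3, 3), sides = 2))
  env[is.na(env)] <- 0
  peaks <- pick_peaks(env, min_dist = round(0.15 * fse))
  # heart sound envelopes show strong peak contrast; a flat envelope
  # (e.g. broadband noise) has no decodable cardiac structure
  if (length(peaks) > 0 &&
      mean(env[peaks]) / stats::median(env) < 2) peaks <- integer(0)
  empty <- cycle_annotation(
    data.frame(s1_start = integer(0), s1_end = integer(0),
               sys_end = integer(0), s2_end = integer(0),
               dia_end = integer(0)), source = "envelope")
  if (length(peaks) < 7) return(empty)
  d <- diff(peaks)
  # assignment a: S1 at odd peak positions; b: S1 at even positions
  sys_a <- d[seq(1, length(d), by = 2)]; dia_a <- d[seq(2, length(d), by = 2)]
  sys_b <- d[seq(2, length(d), by = 2)]; dia_b <- d[seq(1, length(d), by = 2)]
  score_a <- mean(dia_a) - mean(sys_a)
  score_b <- mean(dia_b) - mean(sys_b)
  if (abs(score_a - score_b) > 0.02 * fse) {
    s1_first <- score_a > score_b
  } else {
    s1_first <- stats::var(sys_a) <= stats::var(sys_b)
  }
  s1_idx <- peaks[seq(if (s1_first) 1 else 2, length(peaks), by = 2)]
  s2_idx <- peaks[seq(if (s1_first) 2 else 3, length(peaks), by = 2)]
  # envelope index -> 0-based sample index at fs
  to_samp <- function(i) as.integer(round((i - 0.5) / fse * fs))
  h1 <- round(0.045 * fs); h2 <- round(0.035 * fs)
  rows <- list()
  for (k in seq_len(length(s1_idx) - 1)) {
    s2k <- s2_idx[s2_idx > s1_idx[k] & s2_idx < s1_idx[k + 1]]
    if (length(s2k) != 1) next
    p1 <- to_samp(s1_idx[k]); p2 <- to_samp(s2k)
    p1n <- to_samp(s1_idx[k + 1])
    r <- c(s1_start = p1 - h1, s1_end = p1 + h1,
           sys_end = p2 - h2, s2_end = p2 + h2, dia_end = p1n - h1)
    if (r[1] < 0 || r[5] > M) next
    if (any(diff(r) <= 0)) next
    # physiological plausibility: cycle 0.3-2 s, systole 15-65% of it
    cc <- (r[5] - r[1]) / fs
    sys_frac <- (r[3] - r[2]) / (r[5] - r[1])
    if (cc < 0.3 || cc > 2 || sys_frac < 0.15 || sys_frac > 0.65) next
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) < 3) return(empty)
  cy <- as.data.frame(do.call(rbind, rows))
  cy[] <- lapply(cy, as.integer)
  # cycle lengths of a real rhythm are consistent; reject erratic pickings
  cc <- (cy$dia_end - cy$s1_start) / fs
  if (stats::mad(cc, constant = 1) / stats::median(cc) > 0.2) return(empty)
  cycle_annotation(cy, source = "envelope")
}
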