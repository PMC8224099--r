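#' Single-channel entropy parameters
#'
#' Parameter container for the template-matching entropy estimators.
#'
#' @param m Embedding dimension (template length). Default 2.
#' @param r Matching tolerance as a multiple of the SD of the analysed
#'   slice. Default 0.2.
#' @param B Histogram bin count for the distribution entropy. Default 256.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.2, B = 256L) {
  m <- as.integer(m); B <- as.integer(B)
  stopifnot(m >= 1L, r > 0, B >= 2L)
  structure(list(m = m, r = r, B = B), class = "entropy_params")
}

#' Sample entropy
#'
#' Probability that sequences matching for `m` points also match at point
#' `m + 1`, reported as a negative log. Templates are compared under the
#' Chebyshev (max-norm) distance with an absolute tolerance `r_abs`;
#' self-matches are excluded. When no template pair matches at length
#' `m + 1` the count is replaced by 1/2 (a continuity correction) so a
#' finite cap `log(2 * B_m)` is returned instead of infinity; when nothing
#' matches even at length `m` the statistic is undefined and `NaN` is
#' returned with a warning.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Embedding dimension.
#' @param r_abs Absolute matching tolerance (same units as `x`).
#' @return A single nonnegative number (or `NaN` when undefined).
#' @export
sampen <- function(x, m = 2L, r_abs) {
  x <- as.numeric(x)
  if (length(x) < m + 2L) stop("x must have length >= m + 2")
  if (!all(is.finite(x))) stop("x must be finite")
  stopifnot(r_abs > 0)
  cnt <- cpp_sampen_counts(x, as.integer(m), r_abs)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0) {
    warning("no template matches at dimension m; sample entropy undefined")
    return(NaN)
  }
  if (A == 0) A <- 0.5
  -log(A / B)
}

#' Fuzzy entropy
#'
#' Same framework as [sampen()] with the hard match indicator replaced by
#' the fuzzy membership `exp(-d^2 / r)` of the Chebyshev distance `d`
#' between baseline-removed templates (each template has its own mean
#' subtracted). The input is normalized to unit SD first, so `r` is a
#' tolerance relative to the SD of the series (the convention in which
#' analysed signals are normalized) and the statistic is invariant to
#' amplitude scaling. The default membership follows the printed `d^2`
#' definition; `exponent` switches to the more common `d^n` family.
#'
#' @inheritParams sampen
#' @param r Tolerance in units of the SD of `x` (default 0.2).
#' @param exponent Exponent applied to the distance inside the membership
#'   (default 2).
#' @return A single nonnegative number.
#' @export
fuzzyen <- function(x, m = 2L, r = 0.2, exponent = 2) {
  x <- as.numeric(x)
  if (length(x) < m + 2L) stop("x must have length >= m + 2")
  if (!all(is.finite(x))) stop("x must be finite")
  stopifnot(r > 0)
  s <- stats::sd(x)
  if (is.finite(s) && s > 0) x <- x / s
  if (exponent != 2) {
    # generic-exponent fallback (rarely used): plain R accumulation
    phis <- fuzzyen_phis_r(x, as.integer(m), r, exponent)
  } else {
    phis <- cpp_fuzzyen_phis(x, as.integer(m), r)
  }
  -log(phis[2] / phis[1])
}

# reference-style R accumulation used for non-default membership exponents
fuzzyen_phis_r <- function(x, m, r_abs, expo) {
  nt <- length(x) - m
  tm <- sapply(seq_len(nt), function(i) {
    v <- x[i:(i + m - 1)]; v - mean(v)
  })
  tm1 <- sapply(seq_len(nt), function(i) {
    v <- x[i:(i + m)]; v - mean(v)
  })
  sm <- 0; sm1 <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(tm[, i] - tm[, j]))
      d1 <- max(abs(tm1[, i] - tm1[, j]))
      sm <- sm + exp(-(d^expo) / r_abs)
      sm1 <- sm1 + exp(-(d1^expo) / r_abs)
    }
  }
  np <- nt * (nt - 1) / 2
  c(sm / np, sm1 / np)
}

#' Distribution entropy
#'
#' Normalized Shannon entropy of the empirical distribution of all pairwise
#' Chebyshev distances between `m`-templates (`i != j`), histogrammed into
#' `B` equal-width bins spanning `[0, max distance]`. Bounded in `[0, 1]`;
#' a series whose template distances are all identical scores 0.
#'
#' @inheritParams sampen
#' @param B Number of histogram bins.
#' @return A number in `[0, 1]`.
#' @export
disten <- function(x, m = 2L, B = 256L) {
  x <- as.numeric(x)
  if (length(x) < m + 2L) stop("x must have length >= m + 2")
  if (!all(is.finite(x))) stop("x must be finite")
  stopifnot(B >= 2L)
  cpp_disten(x, as.integer(m), as.integer(B))
}

#' Per-channel entropy feature block
#'
#' Computes SampEn, FuzzyEn and DistEn of the systolic and diastolic slice
#' of every cardiac cycle in one channel, then summarizes each of the six
#' quantities by its mean and (population) SD across cycles: 12 features.
#' Each slice is normalized to mean 0 / SD 1 first, so the tolerance
#' `params$r` is `r` times the slice SD and all three estimators are
#' invariant to channel gain. Cycles on which an estimator is undefined
#' are dropped from the summary; if more than half the cycles are
#' undefined the feature pair is reported as `NA` with a warning.
#'
#' @param seg_channel Numeric vector: one channel of a segment.
#' @param ann A [cycle_annotation()] for that channel.
#' @param params An [entropy_params()] object.
#' @return Named numeric vector of length 12 (`m_SampEn_Sys`,
#'   `sd_SampEn_Sys`, ..., `sd_DistEn_Dia`).
#' @export
entropy_block <- function(seg_channel, ann, params = entropy_params()) {
  sl <- state_slices(seg_channel, ann)
  if (length(sl) < 3L) stop("at least 3 cycles are required")
  per <- vapply(sl, function(cy) {
    out <- rep(NA_real_, 6)
    for (k in 1:2) {
      s <- if (k == 1) cy$systole else cy$diastole
      if (length(s) < params$m + 10L) next
      s_sd <- stats::sd(s)
      if (!is.finite(s_sd) || s_sd <= 0) next
      s <- (s - mean(s)) / s_sd
      out[k]     <- suppressWarnings(sampen(s, params$m, params$r))
      out[2 + k] <- suppressWarnings(fuzzyen(s, params$m, params$r))
      out[4 + k] <- disten(s, params$m, params$B)
    }
    out
  }, numeric(6))
  base <- c("SampEn_Sys", "SampEn_Dia", "FuzzyEn_Sys", "FuzzyEn_Dia",
            "DistEn_Sys", "DistEn_Dia")
  res <- numeric(0)
  for (q in seq_along(base)) {
    v <- per[q, ]
    v <- v[is.finite(v)]
    if (length(v) < ncol(per) / 2) {
      warning(sprintf("entropy feature %s undefined on >50%% of cycles", base[q]))
      mv <- NA_real_; sv <- NA_real_
    } else {
      mv <- mean(v); sv <- pop_sd(v)
    }
    res[paste0("m_", base[q])] <- mv
    res[paste0("sd_", base[q])] <- sv
  }
  res
}

# population SD (divisor n); per-cycle feature summaries use this throughout
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
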