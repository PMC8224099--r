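#' Cross-entropy parameters
#'
#' @param m Embedding dimension. Default 2.
#' @param tau Time delay between template points, in samples. Default 1.
#' @param r Matching tolerance; the channels entering the cross measures are
#'   normalized to unit SD, so `r` is also the absolute tolerance. Default 0.2.
#' @param B Histogram bin count for the joint distribution entropy.
#'   Default 256.
#' @return A list of class `cross_entropy_params`.
#' @export
cross_entropy_params <- function(m = 2L, tau = 1L, r = 0.2, B = 256L) {
  m <- as.integer(m); tau <- as.integer(tau); B <- as.integer(B)
  stopifnot(m >= 1L, tau >= 1L, r > 0, B >= 2L)
  structure(list(m = m, tau = tau, r = r, B = B),
            class = "cross_entropy_params")
}

check_pair <- function(x, y, p) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < p$m * p$tau + 10L) stop("series too short for (m, tau)")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
}

#' Cross-sample entropy of two channels
#'
#' Measures pattern synchrony between two signals: delay-embedded templates
#' of `x` are matched against templates of `y` under the Chebyshev distance
#' with tolerance `r`, and the statistic is the negative log of the ratio
#' of match counts at dimensions `m + 1` and `m`. Symmetric in its
#' arguments. Larger values indicate weaker coupling.
#'
#' @param x,y Numeric vectors of equal length, normalized to mean 0 / SD 1.
#' @param p A [cross_entropy_params()] object.
#' @return A single nonnegative number (`NaN` with a warning when no pair
#'   matches at dimension `m`).
#' @export
xsampen <- function(x, y, p = cross_entropy_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  check_pair(x, y, p)
  cnt <- cpp_xsampen_counts(x, y, p$m, p$tau, p$r)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0) {
    warning("no cross-template matches at dimension m; XSampEn undefined")
    return(NaN)
  }
  if (A == 0) A <- 0.5
  -log(A / B)
}

#' Cross-fuzzy entropy of two channels
#'
#' Same framework as [xsampen()] with the hard match replaced by the
#' Gaussian membership `exp(-ln(2) * (d / r)^2)`, which equals 1/2 exactly
#' at `d = r`. Pairs with `i == j` are excluded from the average.
#'
#' @inheritParams xsampen
#' @return A single nonnegative number.
#' @export
xfuzzyen <- function(x, y, p = cross_entropy_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  check_pair(x, y, p)
  phis <- cpp_xfuzzyen_phis(x, y, p$m, p$tau, p$r)
  -log(phis[2] / phis[1])
}

#' Joint distribution entropy of two channels
#'
#' The joint distance of a template pair `(i, j)` is the geometric mean of
#' the within-`x` and within-`y` Chebyshev template distances, so the
#' measure reduces exactly to [disten()] when the two channels coincide.
#' The joint distances are histogrammed into `B` equal-width bins on
#' `[0, max]` and summarized by the normalized Shannon entropy.
#'
#' @inheritParams xsampen
#' @return A number in `[0, 1]`.
#' @export
jdisten <- function(x, y, p = cross_entropy_params()) {
  x <- as.numeric(x); y <- as.numeric(y)
  check_pair(x, y, p)
  cpp_jdisten(x, y, p$m, p$tau, p$B)
}

#' Cross-entropy feature block over all channel pairs
#'
#' Computes XSampEn, XFuzzyEn and JDistEn for each of the 10 unordered
#' pairs of the 5 channels of a segment: 30 features. The measures are
#' computed on the whole (preprocessed) segment, not per cardiac state.
#' Channels are decimated by `decimate` (anti-aliased) and normalized to
#' mean 0 / SD 1 before embedding.
#'
#' @param seg A [pcg_segment()].
#' @param p A [cross_entropy_params()] object.
#' @param decimate Integer decimation factor applied before the O(N^2)
#'   template comparisons. Default 4 (2 kHz to 500 Hz).
#' @return Named numeric vector of length 30 (`XSampEn_12`, ...,
#'   `JDistEn_45`).
#' @export
cross_block <- function(seg, p = cross_entropy_params(), decimate = 4L) {
  if (!inherits(seg, "pcg_segment")) stop("seg must be a pcg_segment")
  if (nrow(seg$samples) != 5L) stop("all 5 channels must be present")
  ch <- lapply(1:5, function(c) {
    x <- seg$samples[c, ]
    if (decimate > 1L) x <- signal::decimate(x, as.integer(decimate))
    normalize_signal(x)
  })
  pairs <- channel_pairs()
  out <- numeric(0)
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    sfx <- paste0(i, j)
    out[paste0("XSampEn_", sfx)] <- suppressWarnings(xsampen(ch[[i]], ch[[j]], p))
    out[paste0("XFuzzyEn_", sfx)] <- xfuzzyen(ch[[i]], ch[[j]], p)
    out[paste0("JDistEn_", sfx)] <- jdisten(ch[[i]], ch[[j]], p)
  }
  # canonical order: all XSampEn, then XFuzzyEn, then JDistEn
  nm <- cross_feature_names()
  out[nm]
}

channel_pairs <- function() {
  prs <- list()
  for (i in 1:4) for (j in (i + 1):5) prs[[length(prs) + 1L]] <- c(i, j)
  prs
}

cross_feature_names <- function() {
  sfx <- vapply(channel_pairs(), function(p) paste0(p[1], p[2]), "")
  c(paste0("XSampEn_", sfx), paste0("XFuzzyEn_", sfx), paste0("JDistEn_", sfx))
}

#' Tolerance sweep for the cross measures
#'
#' Recomputes XSampEn/XFuzzyEn over a grid of tolerances on one channel
#' pair and also reports the raw template match count at dimension `m`
#' (which is nondecreasing in `r`).
#'
#' @inheritParams xsampen
#' @param r_grid Tolerances to evaluate. Default `c(0.1, 0.15, 0.2, 0.25, 0.3)`.
#' @return A data.frame with columns `r`, `xsampen`, `xfuzzyen`, `matches_m`.
#' @export
cross_r_sweep <- function(x, y, r_grid = c(0.1, 0.15, 0.2, 0.25, 0.3),
                          p = cross_entropy_params()) {
  rows <- lapply(r_grid, function(r) {
    pr <- cross_entropy_params(p$m, p$tau, r, p$B)
    cnt <- cpp_xsampen_counts(as.numeric(x), as.numeric(y), pr$m, pr$tau, pr$r)
    data.frame(r = r,
               xsampen = suppressWarnings(xsampen(x, y, pr)),
               xfuzzyen = xfuzzyen(x, y, pr),
               matches_m = cnt[1])
  })
  do.call(rbind, rows)
}
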