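# Naive reference implementations used as independent oracles: explicit
# double loops over all template pairs, written for clarity not speed.

o_templates <- function(x, m, tau = 1) {
  nt <- length(x) - (m - 1) * tau
  t(sapply(seq_len(nt), function(i) x[i + (0:(m - 1)) * tau]))
}

o_cheb <- function(a, b) max(abs(a - b))

o_sampen <- function(x, m, r) {
  nt <- length(x) - m
  Tm <- o_templates(x, m)[seq_len(nt), , drop = FALSE]
  Tm1 <- o_templates(x, m + 1)[seq_len(nt), , drop = FALSE]
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    if (o_cheb(Tm[i, ], Tm[j, ]) <= r) {
      B <- B + 1
      if (o_cheb(Tm1[i, ], Tm1[j, ]) <= r) A <- A + 1
    }
  }
  if (B == 0) return(NaN)
  if (A == 0) A <- 0.5
  -log(A / B)
}

o_sampen_counts <- function(x, m, r) {
  nt <- length(x) - m
  Tm <- o_templates(x, m)[seq_len(nt), , drop = FALSE]
  Tm1 <- o_templates(x, m + 1)[seq_len(nt), , drop = FALSE]
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    if (o_cheb(Tm[i, ], Tm[j, ]) <= r) B <- B + 1
    if (o_cheb(Tm1[i, ], Tm1[j, ]) <= r) A <- A + 1
  }
  c(B = B, A = A)
}

o_fuzzyen <- function(x, m, r) {
  nt <- length(x) - m
  Tm <- o_templates(x, m)[seq_len(nt), , drop = FALSE]
  Tm1 <- o_templates(x, m + 1)[seq_len(nt), , drop = FALSE]
  Tm <- Tm - rowMeans(Tm)
  Tm1 <- Tm1 - rowMeans(Tm1)
  sm <- 0; sm1 <- 0
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    sm <- sm + exp(-o_cheb(Tm[i, ], Tm[j, ])^2 / r)
    sm1 <- sm1 + exp(-o_cheb(Tm1[i, ], Tm1[j, ])^2 / r)
  }
  -log(sm1 / sm)
}

o_disten <- function(x, m, B) {
  Tm <- o_templates(x, m)
  nt <- nrow(Tm)
  d <- c()
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt)
    d <- c(d, o_cheb(Tm[i, ], Tm[j, ]))
  dmax <- max(d)
  if (dmax <= 0) return(0)
  bin <- pmin(floor(d / dmax * B), B - 1)
  p <- tabulate(bin + 1, nbins = B) / length(d)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(B)
}

o_xsampen <- function(x, y, m, tau, r) {
  nt <- length(x) - m * tau
  Tx <- o_templates(x, m, tau)[seq_len(nt), , drop = FALSE]
  Ty <- o_templates(y, m, tau)[seq_len(nt), , drop = FALSE]
  Tx1 <- o_templates(x, m + 1, tau)
  Ty1 <- o_templates(y, m + 1, tau)
  B <- 0; A <- 0
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (o_cheb(Tx[i, ], Ty[j, ]) <= r) {
      B <- B + 1
      if (o_cheb(Tx1[i, ], Ty1[j, ]) <= r) A <- A + 1
    }
  }
  if (B == 0) return(NaN)
  if (A == 0) A <- 0.5
  -log(A / B)
}

o_xfuzzyen <- function(x, y, m, tau, r) {
  nt <- length(x) - m * tau
  Tx <- o_templates(x, m, tau)[seq_len(nt), , drop = FALSE]
  Ty <- o_templates(y, m, tau)[seq_len(nt), , drop = FALSE]
  Tx1 <- o_templates(x, m + 1, tau)
  Ty1 <- o_templates(y, m + 1, tau)
  sm <- 0; sm1 <- 0
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    sm <- sm + exp(-log(2) * (o_cheb(Tx[i, ], Ty[j, ]) / r)^2)
    sm1 <- sm1 + exp(-log(2) * (o_cheb(Tx1[i, ], Ty1[j, ]) / r)^2)
  }
  -log(sm1 / sm)
}

o_jdisten <- function(x, y, m, tau, B) {
  Tx <- o_templates(x, m, tau)
  Ty <- o_templates(y, m, tau)
  nt <- nrow(Tx)
  d <- c()
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt)
    d <- c(d, sqrt(o_cheb(Tx[i, ], Tx[j, ]) * o_cheb(Ty[i, ], Ty[j, ])))
  dmax <- max(d)
  if (dmax <= 0) return(0)
  bin <- pmin(floor(d / dmax * B), B - 1)
  p <- tabulate(bin + 1, nbins = B) / length(d)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(B)
}

# band power fraction via periodogram, for spectral oracles
o_bandpower_frac <- function(x, fs, lo = -Inf, hi = Inf) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- seq_len(n %/% 2 + 1)
  p <- p[half]
  f <- (half - 1) * fs / n
  sum(p[f > lo & f < hi]) / sum(p)
}
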