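test_that("xsampen matches brute force, including the self-pair reduction", {
  p <- cross_entropy_params()
  set.seed(51)
  for (n in c(40, 100, 200)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_identical(xsampen(x, y, p), o_xsampen(x, y, 2, 1, 0.2))
    # identical channels: equals a SampEn-with-self-matches computation
    expect_identical(xsampen(x, x, p), o_xsampen(x, x, 2, 1, 0.2))
  }
  p2 <- cross_entropy_params(m = 3, tau = 2, r = 0.3)
  x <- rnorm(80); y <- rnorm(80)
  expect_identical(xsampen(x, y, p2), o_xsampen(x, y, 3, 2, 0.3))
})

test_that("independent noise raises xsampen above the coupled case", {
  base <- rep(c(1, 2, 3, 2, 1, 2, 3, 2), 8)
  base <- as.numeric(scale(base))
  set.seed(52)
  noisy <- as.numeric(scale(base + rnorm(length(base), 0, 2)))
  p <- cross_entropy_params()
  expect_gt(o_xsampen(base, noisy, 2, 1, 0.2), o_xsampen(base, base, 2, 1, 0.2))
  expect_gt(xsampen(base, noisy, p), xsampen(base, base, p))
})

test_that("xfuzzyen matches brute force and its membership halves at d = r", {
  p <- cross_entropy_params()
  set.seed(53)
  for (n in c(40, 100)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(xfuzzyen(x, y, p), o_xfuzzyen(x, y, 2, 1, 0.2),
                 tolerance = 1e-10)
  }
  # the Gaussian membership is forced to 1/2 exactly at distance r
  r <- 0.37
  expect_identical(exp(-log(2) * (r / r)^2), 0.5)
})

test_that("jdisten matches the joint-distance-matrix oracle and reduces to disten", {
  p <- cross_entropy_params(B = 64)
  set.seed(54)
  for (n in c(30, 60)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(jdisten(x, y, p), o_jdisten(x, y, 2, 1, 64), tolerance = 1e-12)
    # y = x: joint distance sqrt(d * d) = d, exactly DistEn
    expect_identical(jdisten(x, x, p), disten(x, 2, 64))
  }
})

test_that("all three cross measures are symmetric and bounded", {
  p <- cross_entropy_params()
  set.seed(55)
  for (k in 1:10) {
    x <- rnorm(120); y <- rnorm(120)
    expect_identical(xsampen(x, y, p), xsampen(y, x, p))
    expect_identical(xfuzzyen(x, y, p), xfuzzyen(y, x, p))
    expect_identical(jdisten(x, y, p), jdisten(y, x, p))
    expect_gte(xsampen(x, y, p), 0)
    expect_gte(xfuzzyen(x, y, p), 0)
    v <- jdisten(x, y, p)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("channel decoupling raises jdisten on heart-sound segments", {
  # matched recordings differing only in dyssynchrony; mean over the 10
  # channel pairs rises with decoupling in every replicate
  deltas <- sapply(1:3, function(s) {
    pf0 <- subject_profile("D", "CAD", murmur_snr_db = -10,
                           desync_level = 0, seed = 600 + s)
    pf1 <- subject_profile("D", "CAD", murmur_snr_db = -10,
                           desync_level = 0.8, seed = 600 + s)
    g <- generate_recording(pf0, duration_s = 10)
    r0 <- preprocess_recording(inject_cad_signature(g$recording, g$states, pf0))
    r1 <- preprocess_recording(inject_cad_signature(g$recording, g$states, pf1))
    cb0 <- cross_block(crop_segments(r0)[[1]])
    cb1 <- cross_block(crop_segments(r1)[[1]])
    jd <- function(v) mean(v[grep("^JDistEn", names(v))])
    jd(cb1) - jd(cb0)
  })
  expect_true(all(deltas > 0))
})

test_that("template match counts are nondecreasing in the tolerance r", {
  set.seed(57)
  x <- rnorm(400); y <- rnorm(400)
  sw <- cross_r_sweep(x, y)
  expect_equal(sw$r, c(0.1, 0.15, 0.2, 0.25, 0.3))
  expect_true(all(diff(sw$matches_m) >= 0))
})

test_that("cross_block emits the 30 canonical pair features", {
  fx <- fixture_segment()
  cb <- cross_block(fx$seg)
  expect_length(cb, 30)
  expect_identical(names(cb), c(
    paste0("XSampEn_", c("12","13","14","15","23","24","25","34","35","45")),
    paste0("XFuzzyEn_", c("12","13","14","15","23","24","25","34","35","45")),
    paste0("JDistEn_", c("12","13","14","15","23","24","25","34","35","45"))))
  expect_true(all(is.finite(cb)))
  # five identical channels: exchange symmetry makes all pairs equal
  seg_same <- fx$seg
  for (c in 2:5) seg_same$samples[c, ] <- seg_same$samples[1, ]
  cbs <- cross_block(seg_same)
  xs <- cbs[grep("^XSampEn", names(cbs))]
  expect_true(all(abs(xs - xs[1]) < 1e-12))
})

test_that("dyssynchrony raises cross entropy between channel pairs", {
  pf0 <- subject_profile("D", "CAD", murmur_snr_db = -10, desync_level = 0,
                         seed = 99)
  pf1 <- subject_profile("D", "CAD", murmur_snr_db = -10, desync_level = 0.8,
                         seed = 99)
  g <- generate_recording(pf0, duration_s = 10)
  r0 <- preprocess_recording(inject_cad_signature(g$recording, g$states, pf0))
  r1 <- preprocess_recording(inject_cad_signature(g$recording, g$states, pf1))
  s0 <- crop_segments(r0)[[1]]; s1 <- crop_segments(r1)[[1]]
  p <- cross_entropy_params()
  x0 <- normalize_signal(signal::decimate(s0$samples[1, ], 4))
  y0 <- normalize_signal(signal::decimate(s0$samples[2, ], 4))
  x1 <- normalize_signal(signal::decimate(s1$samples[1, ], 4))
  y1 <- normalize_signal(signal::decimate(s1$samples[2, ], 4))
  expect_gt(xsampen(x1, y1, p), xsampen(x0, y0, p))
})
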