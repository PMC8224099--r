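test_that("a jitter-free 60 bpm profile yields exactly one cycle per second", {
  pf <- subject_profile("S", "non-CAD", heart_rate_bpm = 60, hr_jitter = 0,
                        seed = 3)
  g <- generate_recording(pf, duration_s = 10)
  expect_identical(n_cycles(g$states), 10L)
  expect_identical(ncol(g$recording$samples), 20000L)
})

test_that("generation is bit-identical for identical profiles", {
  pf <- subject_profile("S", "CAD", murmur_snr_db = -4, desync_level = 0.5,
                        seed = 7)
  g1 <- generate_recording(pf, duration_s = 8)
  g2 <- generate_recording(pf, duration_s = 8)
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$states$cycles, g2$states$cycles)
  i1 <- inject_cad_signature(g1$recording, g1$states, pf)
  i2 <- inject_cad_signature(g2$recording, g2$states, pf)
  expect_identical(i1$samples, i2$samples)
})

test_that("jittered cycle lengths average to the nominal cycle", {
  pf <- subject_profile("S", "non-CAD", heart_rate_bpm = 75, hr_jitter = 0.05,
                        seed = 13)
  g <- generate_recording(pf, duration_s = 300)
  cc <- (g$states$cycles$dia_end - g$states$cycles$s1_start) / 2000
  se <- sd(cc) / sqrt(length(cc))
  expect_lt(abs(mean(cc) - 0.8), 3 * se)
})

test_that("ground-truth states tile each recording contiguously", {
  for (seed in c(1, 2)) {
    pf <- subject_profile("S", "non-CAD", heart_rate_bpm = 70 + 10 * seed,
                          hr_jitter = 0.04, seed = seed)
    g <- generate_recording(pf, duration_s = 12)
    cy <- g$states$cycles
    m <- as.matrix(cy)
    expect_true(all(apply(m, 1, function(r) all(diff(r) > 0))))
    expect_identical(cy$s1_start[-1], cy$dia_end[-nrow(cy)])
    expect_lte(max(cy$dia_end), ncol(g$recording$samples))
  }
})

test_that("generator rejects invalid profiles and durations", {
  expect_error(subject_profile(heart_rate_bpm = 30), "40")
  expect_error(subject_profile(channel_gains = c(1, 1, -1, 1, 1)), "positive")
  pf <- subject_profile(heart_rate_bpm = 60)
  expect_error(generate_recording(pf, duration_s = 2), "3 cardiac cycles")
  expect_error(inject_cad_signature(generate_recording(pf, 5)$recording,
                                    NULL, pf), "CAD")
})

test_that("null injection returns the recording unchanged", {
  pf <- subject_profile("S", "CAD", murmur_snr_db = -Inf, desync_level = 0,
                        seed = 5)
  g <- generate_recording(pf, duration_s = 6)
  out <- inject_cad_signature(g$recording, g$states, pf)
  expect_identical(out$samples, g$recording$samples)
})

test_that("murmur injection raises diastolic 200-800 Hz band power", {
  pf <- subject_profile("S", "CAD", murmur_snr_db = 0, desync_level = 0,
                        seed = 9)
  g <- generate_recording(pf, duration_s = 10)
  inj <- inject_cad_signature(g$recording, g$states, pf)
  cy <- g$states$cycles
  band_dia <- function(x) {
    mean(sapply(seq_len(nrow(cy)), function(k) {
      sl <- x[(cy$s2_end[k] + 1):cy$dia_end[k]]
      o_bandpower_frac(sl, 2000, 200, 800) * mean(sl^2)
    }))
  }
  for (c in c(1, 3, 5))
    expect_gt(band_dia(inj$samples[c, ]), band_dia(g$recording$samples[c, ]))
})

test_that("higher dyssynchrony strictly raises pairwise cross entropy", {
  p <- cross_entropy_params()
  vals <- sapply(c(0, 0.8), function(d) {
    pf <- subject_profile("S", "CAD", murmur_snr_db = -8, desync_level = d,
                          seed = 21)
    g <- generate_recording(pf, duration_s = 10)
    inj <- inject_cad_signature(g$recording, g$states, pf)
    x <- normalize_signal(signal::decimate(inj$samples[1, ], 4))
    y <- normalize_signal(signal::decimate(inj$samples[2, ], 4))
    xsampen(x, y, p)
  })
  expect_gt(vals[2], vals[1])
})

test_that("cohorts have the requested composition and are reproducible", {
  coh <- generate_cohort(3, 2, seed = 77, duration_s = 6)
  expect_length(coh, 5)
  labs <- vapply(coh, function(s) s$profile$label, "")
  expect_identical(sum(labs == "CAD"), 3L)
  coh2 <- generate_cohort(3, 2, seed = 77, duration_s = 6)
  expect_identical(coh[[1]]$recording$samples, coh2[[1]]$recording$samples)
  expect_identical(coh[[5]]$recording$samples, coh2[[5]]$recording$samples)
  expect_error(generate_cohort(-1, 2, seed = 1), "nonnegative")
  solo <- generate_cohort(0, 1, seed = 3, duration_s = 6)
  expect_length(solo, 1)
  expect_identical(solo[[1]]$profile$label, "non-CAD")
  expect_identical(solo[[1]]$profile$murmur_snr_db, -Inf)
})

test_that("CAD and non-CAD groups separate on murmur and synchrony features", {
  # strong-signature conditions: murmur at 0 dB, dyssynchrony 0.6
  p <- cross_entropy_params()
  feat <- function(label, seed) {
    fx <- make_segment(label, seed = seed, murmur_snr_db = 0,
                       desync_level = 0.6)
    ff <- frequency_domain_features(fx$seg$samples[2, ], fx$ann, 2000)
    x <- normalize_signal(signal::decimate(fx$seg$samples[1, ], 4))
    y <- normalize_signal(signal::decimate(fx$seg$samples[2, ], 4))
    c(hf = ff[["m_HFAll_Dia"]], xs = xsampen(x, y, p))
  }
  cad <- sapply(1:4, function(s) feat("CAD", 400 + s))
  non <- sapply(1:4, function(s) feat("non-CAD", 500 + s))
  expect_gt(mean(cad["hf", ]), mean(non["hf", ]))
  expect_gt(mean(cad["xs", ]), mean(non["xs", ]))
})
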