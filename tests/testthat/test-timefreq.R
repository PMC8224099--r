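test_that("time features recover the generator's timing exactly", {
  fx <- make_segment(seed = 91, heart_rate_bpm = 60, hr_jitter = 0)
  tf <- time_domain_features(fx$seg$samples[1, ], fx$ann, 2000)
  expect_length(tf, 20)
  expect_equal(tf[["m_CC"]], 1.0, tolerance = 1e-3)
  expect_identical(tf[["sd_CC"]], 0)
  expect_equal(tf[["m_Ratio_SysCC"]], 0.35, tolerance = 0.01)
  expect_equal(tf[["m_Ratio_DiaCC"]], 0.49, tolerance = 0.01)
  # gain invariance: durations and amplitude *ratios* are scale free
  tf2 <- time_domain_features(7 * fx$seg$samples[1, ], fx$ann, 2000)
  expect_equal(tf, tf2, tolerance = 1e-12)
})

test_that("per-cycle time features agree with direct arithmetic", {
  fx <- make_segment(seed = 92, heart_rate_bpm = 80, hr_jitter = 0.04)
  cy <- fx$ann$cycles
  tf <- time_domain_features(fx$seg$samples[2, ], fx$ann, 2000)
  cc <- (cy$dia_end - cy$s1_start) / 2000
  expect_identical(tf[["m_CC"]], mean(cc))
  expect_identical(tf[["sd_CC"]], sqrt(mean((cc - mean(cc))^2)))
  sys <- (cy$sys_end - cy$s1_end) / 2000
  expect_identical(tf[["m_Ratio_SysCC"]], mean(sys / cc))
  x <- fx$seg$samples[2, ]
  amp_sys <- sapply(seq_len(nrow(cy)), function(k)
    mean(abs(x[(cy$s1_end[k] + 1):cy$sys_end[k]])))
  amp_s1 <- sapply(seq_len(nrow(cy)), function(k)
    mean(abs(x[(cy$s1_start[k] + 1):cy$s1_end[k]])))
  expect_identical(tf[["m_Amp_SysS1"]], mean(amp_sys / amp_s1))
})

test_that("spectrum proportions follow a two-line Parseval oracle", {
  fs <- 2000
  t <- (1:4096) / fs
  hi <- state_spectrum_proportions(sin(2 * pi * 300 * t), fs)
  expect_gt(hi[["hf_prop"]], 0.99)
  expect_lt(hi[["lf_prop"]], 0.01)
  lo <- state_spectrum_proportions(sin(2 * pi * 40 * t), fs)
  expect_gt(lo[["lf_prop"]], 0.99)
  both <- state_spectrum_proportions(sin(2 * pi * 40 * t) +
                                       sin(2 * pi * 300 * t), fs)
  expect_equal(both[["hf_prop"]], 0.5, tolerance = 0.02)
  expect_equal(both[["lf_prop"]], 0.5, tolerance = 0.02)
  expect_error(state_spectrum_proportions(rnorm(8), fs), "short")
})

test_that("band proportions are disjoint, bounded and scale invariant", {
  set.seed(93)
  for (k in 1:20) {
    x <- rnorm(500)
    pr <- state_spectrum_proportions(x, 2000)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_lte(pr[["hf_prop"]] + pr[["lf_prop"]], 1)
    expect_equal(pr, state_spectrum_proportions(10 * x, 2000),
                 tolerance = 1e-12)
  }
})

test_that("frequency features separate murmur from clean diastole", {
  fx0 <- make_segment("non-CAD", seed = 94)
  ff0 <- frequency_domain_features(fx0$seg$samples[2, ], fx0$ann, 2000)
  expect_length(ff0, 16)
  expect_lt(ff0[["m_HFAll_Dia"]], 0.1)
  fx1 <- make_segment("CAD", seed = 94, murmur_snr_db = 0, desync_level = 0)
  ff1 <- frequency_domain_features(fx1$seg$samples[2, ], fx1$ann, 2000)
  expect_gt(ff1[["m_HFAll_Dia"]], ff0[["m_HFAll_Dia"]])
  # per-cycle mean agrees with a direct bandpower oracle
  sl <- state_slices(fx0$seg$samples[2, ], fx0$ann)
  hf <- sapply(sl, function(cy) o_bandpower_frac(cy$diastole, 2000, lo = 200))
  expect_equal(ff0[["m_HFAll_Dia"]], mean(hf), tolerance = 1e-12)
})

test_that("degenerate identical cycles give zero feature dispersion", {
  # build a segment whose cycles are exact copies
  fs <- 2000
  cyc_len <- fs  # 1 s
  t <- (1:cyc_len) / fs
  one <- sin(2 * pi * 50 * t) * exp(-0.5 * ((t - 0.09) / 0.02)^2) +
    0.5 * sin(2 * pi * 90 * t) * exp(-0.5 * ((t - 0.48) / 0.02)^2) + 1e-3
  x <- rep(one, 5)
  cy <- data.frame(s1_start = (0:4) * cyc_len,
                   s1_end = (0:4) * cyc_len + 180,
                   sys_end = (0:4) * cyc_len + 880,
                   s2_end = (0:4) * cyc_len + 1020,
                   dia_end = (1:5) * cyc_len)
  ann <- cycle_annotation(cy, source = "ground_truth")
  tf <- time_domain_features(x, ann, fs)
  ff <- frequency_domain_features(x, ann, fs)
  eb <- entropy_block(x, ann)
  expect_true(all(tf[grep("^sd_", names(tf))] == 0))
  expect_true(all(ff[grep("^sd_", names(ff))] == 0))
  expect_true(all(eb[grep("^sd_", names(eb))] == 0))
  expect_error(time_domain_features(x, cycle_annotation(cy[1:2, ],
                                                        "ground_truth"), fs),
               "3 cycles")
})
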