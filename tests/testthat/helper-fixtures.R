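# Shared fixtures built in code. Heavy objects are memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# one preprocessed segment + matching ground-truth annotation
make_segment <- function(label = "non-CAD", seed = 1, heart_rate_bpm = 75,
                         hr_jitter = 0.03, murmur_snr_db = -6,
                         desync_level = 0.6, duration_s = 10,
                         preprocess = TRUE, which_seg = 1) {
  pf <- subject_profile("T1", label, heart_rate_bpm = heart_rate_bpm,
                        hr_jitter = hr_jitter,
                        murmur_snr_db = if (label == "CAD") murmur_snr_db else -Inf,
                        desync_level = if (label == "CAD") desync_level else 0,
                        seed = seed)
  g <- generate_recording(pf, duration_s = duration_s)
  rec <- g$recording
  if (label == "CAD") rec <- inject_cad_signature(rec, g$states, pf)
  if (preprocess) rec <- preprocess_recording(rec)
  seg <- crop_segments(rec)[[which_seg]]
  ann <- segment_states(seg, truth = g$states)
  list(seg = seg, ann = ann, profile = pf, states = g$states)
}

fixture_segment <- function() memo("seg_noncad", function() make_segment(seed = 301))
fixture_segment_cad <- function() memo("seg_cad", function()
  make_segment("CAD", seed = 302))

# the 270-column feature row of the shared segment (cross block at the
# package default decimation)
fixture_row <- function() memo("row_noncad", function() {
  fx <- fixture_segment()
  extract_features(fx$seg, fx$ann)
})

# the evaluation cohort: 21 CAD / 15 non-CAD subjects, 20 s each; cross
# entropy at decimation 8 to keep the suite fast (see vignette)
fixture_cohort_table <- function() memo("cohort_tab", function() {
  coh <- generate_cohort(21, 15, seed = 2024, duration_s = 20)
  extract_feature_table(coh, cfg = pipeline_config(cross_decimate = 8L))
})
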