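---
title: "Multi-domain feature fusion of multi-channel heart sounds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain feature fusion of multi-channel heart sounds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coronary artery disease (CAD) narrows coronary vessels; blood forced
through a stenosis becomes turbulent and radiates weak broadband murmurs,
predominantly in the 200–800 Hz band, that are audible in the
phonocardiogram (PCG) during systole and diastole. Ischemic myocardium
also contracts less synchronously, which shows up as reduced coupling
between heart sound signals recorded simultaneously at different chest
locations. This package implements an analysis pipeline that exploits both
effects: five-channel PCG recordings are preprocessed, segmented into
cardiac states (S1, systole, S2, diastole), condensed into a 270-column
feature table spanning four domains (time, frequency, single-channel
entropy, two-channel cross entropy), and classified subject-wise with an
RBF-kernel SVM after feature selection.

Because the clinical recordings that motivated this design are private,
the package ships a synthetic five-channel PCG generator that emulates the
statistical structure the analysis relies on, with known ground truth.
Every pipeline stage is exercised and validated against that generator.

## Pipeline and parameters

**Preprocessing.** A fifth-order Butterworth high-pass at 30 Hz removes
baseline drift and respiration; a 50 Hz biquad notch (Q = 30) removes
mains interference. Both filters are applied forward–backward: zero-phase
filtering keeps state boundaries aligned with ground-truth annotations,
which matters because features are computed on annotated state windows.
Filtering precedes cropping. Recordings are cropped to non-overlapping
10-s segments (a 5-minute recording gives 30), and each segment passes a
quality gate of three per-channel metrics: clipping fraction (share of
samples within 1% of the channel's rail; limit 0.01), spectral flatness
(geometric/arithmetic periodogram mean; limit 0.5 — white noise
approaches 1, structured heart sound is far lower) and the envelope
autocorrelation peak in the 0.4–1.5 s lag band (evidence of cardiac
periodicity; minimum 0.15). The reference quality criteria of the original
protocol are not public; this three-metric rule is the package's own
substitute, with thresholds in `quality_thresholds()` rather than in code.

**State segmentation.** State-of-the-art PCG segmentation uses a
pretrained duration-HSMM with logistic-regression emissions;
re-implementing a trained published model (and its training data) is out
of scope here, and that substitution is this package's major
simplification. For synthetic data the generator's exact
ground-truth states are passed through (the default). For data without
ground truth, a Shannon-energy envelope segmenter is provided: the
normalized signal's Shannon energy is smoothed (20 ms), downsampled to
50 Hz, peaks are picked with a 0.15 s separation, and peaks alternate
between S1 and S2 using the physiological rule that diastole (S2→S1) is
longer than systole (S1→S2); near ties are broken by minimizing the
variance of the systolic intervals. Fixed-width windows (S1 ±45 ms,
S2 ±35 ms) delimit the states; incomplete boundary cycles are dropped,
and a segment with fewer than three detected cycles is flagged unusable.
On clean synthetic segments the envelope segmenter recovers ≥90% of S1
onsets within 50 ms of ground truth.

**Features.** All per-cycle quantities are summarized by their mean and
population SD (divisor *n*) across the cycles of a segment; segments need
at least three complete cycles.

* *Time domain (20/channel):* cycle, S1, S2, systolic and diastolic
  durations (s); ratios systole/cycle, diastole/cycle, systole/diastole;
  mean-absolute-amplitude ratios systole/S1 and diastole/S2.
* *Frequency domain (16/channel):* per state (S1, S2, systole, diastole),
  the proportion of spectral *power* above 200 Hz and below 50 Hz.
  "Proportion of a component in the spectrum" is interpreted as a power
  (not amplitude) proportion — the Parseval-consistent convention of the
  high-frequency-energy literature. No taper is applied to the short
  state slices (a Hann option exists in `state_spectrum_proportions()`
  callers by pre-windowing).
* *Entropy (12/channel):* SampEn, FuzzyEn and DistEn of each systolic and
  diastolic slice, computed per cycle then averaged. Parameters follow
  the usual short-series convention: embedding m = 2, tolerance r = 0.2
  in units of the slice SD (slices are normalized before estimation, so
  all three estimators are gain invariant), histogram bins B = 2^8 for
  DistEn. Distances are Chebyshev (max-norm) throughout — the convention
  of the SampEn/FuzzyEn/DistEn literature. The FuzzyEn membership is
  implemented exactly as the printed `exp(-d^2/r)` form, with a switch
  (`exponent`) for the canonical `d^n` family; FuzzyEn templates are
  baseline-removed (own mean subtracted).
* *Cross entropy (30/segment):* XSampEn, XFuzzyEn and JDistEn for each of
  the 10 unordered channel pairs, computed on the whole 10-s segment
  (the analysis does not restrict cross features to a cardiac state).
  Defaults m = 2, τ = 1 (the delay has no canonical value and is exposed
  in `cross_entropy_params()`), r = 0.2 on normalized channels, B = 2^8.
  The XFuzzyEn membership `exp(-ln 2 (d/r)^2)` equals 1/2 exactly at
  d = r. For JDistEn several joint-distance constructions exist in the
  literature; this package uses the geometric mean of the
  within-channel template distances, chosen because it reduces *exactly*
  to DistEn when the two channels coincide — the package's single
  largest interpretive decision.
  At 2 kHz a 10-s segment has 20,000 samples; since the template
  comparisons are O(N²), channels are decimated by 4 (anti-aliased, to
  500 Hz) before cross-entropy computation. The decimation factor is a
  documented knob, and the estimators are oracle-tested independently of
  it.

All estimator cores are written in C++ with streaming accumulation; no
N×N distance structure is materialized. Degenerate cases are defined
explicitly: constant series score 0 for all three single-channel
estimators; a SampEn/XSampEn numerator of zero is replaced by 1/2 (a
continuity correction yielding a finite cap) and a zero denominator
yields NaN with a warning; DistEn/JDistEn histograms span [0, max
distance] with the diagonal excluded, and a zero maximum distance scores
0.

**Feature sets.** Sin1 (one channel, time+frequency; 36 columns), Sin2
(one channel plus entropy; 48), Mul1 (five channels, time+frequency;
180), Mul2 (all single-channel features; 240), Mul3 (Mul2 plus cross
entropy; 270).

**Selection and classification.** Features are ranked either by
information gain (label entropy minus conditional entropy, base 2, with
equal-frequency discretization into 10 bins — the discretization is the
package's choice) or by SVM-RFE (iterative elimination of the
lowest-|w|² features of a linear-kernel SVM; the final classifier is RBF
but elimination uses the standard linear-weight criterion). Evaluation is
subject-wise stratified 5-fold CV: subjects, never segments, are
partitioned, so no individual contributes to both training and test
data. Within each training fold, features are standardized with
training-fold statistics, ranked (per fold, to avoid selection leakage; a
`global_ranking` flag reproduces the optimistic protocol), truncated to
the top *n*, and an RBF SVM with balanced class weights is tuned over a
C/γ grid of powers of two from 2^-5 to 2^5 by inner 5-fold accuracy.
Metrics are sensitivity, specificity and accuracy in percent with CAD
positive, averaged over the outer folds.

## The synthetic generator

Each cardiac cycle is laid out with fixed fractions of the cycle length:
S1 9%, systole 35%, S2 7%, diastole 49% — so duration-ratio features are
scale-free and systole/CC sits at the physiological 0.35. S1 is a
Gaussian-enveloped multi-sine wavelet with components at 35/60/90 Hz, S2
at 60/100/140 Hz with 0.8 relative amplitude; both get ±5% per-cycle
amplitude jitter shared across channels. Cycle lengths are jittered with
i.i.d. Gaussian noise truncated at ±3 SD (no long-range heart-rate
variability). The five channels are gain-scaled, time-aligned copies with
channel-specific morphology perturbations (±3% frequency scaling, random
component phases). Always-present contaminants give the preprocessing
stage something to remove: a 0.2 Hz respiration drift (amplitude 0.3), a
50 Hz mains component (amplitude 0.05) and a pink-noise baseline rolled
off above 80 Hz, so that a clean diastole carries essentially no energy
above 200 Hz. Two benign subject-level noise sources create realistic
between-subject variance: a broadband 150–600 Hz floor (default −6 dB
relative to the baseline rumble) and channel-independent sensor noise
(default SD 0.01 of the unit burst amplitude) — the latter gives
cross-entropy features non-degenerate variance in the non-CAD group.

The CAD signature has two components, injected only for CAD subjects:

* *Murmur:* band-limited 200–800 Hz noise added during systole and
  diastole at `murmur_snr_db` relative to the high-passed in-window
  signal power, with a lognormal per-channel "site audibility" gain
  (SD 0.8 on the log scale) — murmurs are weak and are not equally
  audible at all auscultation sites, which is precisely why multi-site
  recording helps.
* *Dyssynchrony:* the murmur is split into shared and channel-independent
  components with weights √(1−d)/√d at dyssynchrony level d, the shared
  part is phase-jittered per channel, and channel-independent 30–200 Hz
  noise proportional to d is mixed into the whole recording. Pairwise
  XSampEn/XFuzzyEn/JDistEn increase with d by construction.

**Cohort conditions.** The default evaluation cohort is 21 CAD and 15
non-CAD subjects, a typical clinical case-control composition at this
scale. Per-subject draws:
heart rate ~ N(75, 10) bpm clipped to [55, 110]; cycle jitter
~ U(0.02, 0.06); per-channel gains lognormal (SD 0.2) around the fixed
site pattern; benign high-frequency floor ~ N(−5, 3) dB; sensor noise
lognormal (SD 0.6) around 0.01; for CAD subjects, murmur SNR ~ N(−9, 4)
dB and dyssynchrony ~ U(0.15, 0.7). These distributions were chosen once,
while designing the generator, so that the cohort sits in the regime
clinical heart-sound studies report — single-channel accuracy in the high 70s to low
90s, multi-channel higher, neither at ceiling — with class overlap coming
from weak-murmur CAD subjects and noisy non-CAD subjects. They are not
calibrated to any private dataset, and the acceptance checks were not
used to tune them.

**What the generator does not emulate:** real murmur morphology (it is
band-limited noise, not turbulence), valvular disease, ECG timing,
long-range heart-rate variability, respiration-gated amplitude
modulation, intermittent artifacts (speech, rubbing), or realistic
inter-subject anatomy. Passing tests on this cohort therefore show that
the *pipeline* behaves as specified — estimators exact, protocol
leak-free, effect directions correct, fusion ordering reproduced under
conditions where it should hold — not that clinically reported
accuracies transfer to real recordings.

## Problem sizes and numerical choices

The packaged checks and the analysis scripts run the full pipeline at
desk scale: 30 s (analysis) or 20 s (tests) per subject instead of 5
minutes, cross-entropy decimation 8 (to 250 Hz) in the test cohort
instead of the default 4, 3-fold inner CV on a coarsened 2^{−3..3}
hyper-parameter grid (factor-4 spacing) instead of the full 11×11 grid,
and information-gain ranking with 30 retained features for the headline
feature-set comparison. These sizes were chosen so the whole analysis reruns in
minutes on one core; the full-scale protocol remains available through
function arguments (`duration_s = 300`, `svm_grid()`, `inner_k = 5`,
`evaluate_sweep()`).

Numerical details worth knowing: per-cycle summaries use the population
SD; spectra are computed per cycle and averaged (not on concatenated
states); entropy tolerances are relative to the SD of the analysed slice;
the information-gain discretization merges duplicate quantile breaks; the
SVM-RFE elimination uses cost 1 with balanced class weights and removes
`elimination_step` features per iteration (the final batch may be
smaller); subject folds are stratified by label with remainder subjects
spread round-robin. The envelope segmenter's S1/S2 disambiguation margin
is 2% of the envelope rate; below it, the systolic-interval-variance
tie-break applies.

## Known limitations

* The envelope segmenter is a deliberately simple substitute for a
  trained duration-HSMM decoder; it assumes reasonably clean recordings
  and alternating S1/S2 peaks, and will mis-segment heavily murmurous or
  arrhythmic signals. Ground-truth pass-through should be used whenever
  annotations exist.
* JDistEn follows this package's geometric-mean joint distance; other
  joint-distance constructions would give numerically different (though
  monotonically related) values. Its response to decoupling is
  construction-dependent: on heart-sound-like signals it rises with
  dyssynchrony (the direction the analysis relies on), but for pure
  sinusoids a coupled pair can score *higher* than independent noise,
  because a sinusoid's template-distance distribution is intrinsically
  broad.
* With 36 subjects and a handful of segments each, fold-level metrics are
  noisy; conclusions should be read from averages over repetitions, as
  the evaluation functions encourage.
* The generator's class structure is, by design, simpler than clinical
  reality; absolute accuracies on synthetic cohorts are not comparable to
  accuracies on patients.
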