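---
title: "Methods: awake OSA screening from tracheal breathing sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: awake OSA screening from tracheal breathing sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Obstructive sleep apnea (OSA) — repetitive partial or complete collapse of
the upper airway during sleep — is severely underdiagnosed because the
reference diagnostic, overnight polysomnography, is slow and expensive.
Tracheal breathing sounds (TBS) recorded over the suprasternal notch
*during wakefulness* carry information about upper-airway anatomy and
collapsibility, and can be captured in minutes with an inexpensive
microphone. The catch is that cheap microphones in ordinary clinical rooms
yield noisy recordings (typical phase SNR around 10 dB), which defeats
naive spectral classifiers.

`osascreen` implements a two-level ensemble framework built for exactly
this regime:

1. **Level 1** — nine *sub-classifiers*, one per anthropometric stratum
   (sex, age above/below 50, BMI above/below 35, Mallampati score
   above/below II, non-current smokers). Each is an ensemble of bagged
   decision trees trained on balanced subsets of its stratum, using seven
   stability-selected acoustic features plus three anthropometric ones
   (neck circumference, snoring, receding mandible).
2. **Level 2** — dynamic selection: for a subject `x`, only the
   sub-classifiers whose stratum predicate `x` satisfies (the set `Kx`,
   of size 4 or 5) are queried, and their OSA probabilities are averaged.
   `p >= 0.5` labels the subject OSA.

Class labels come from the apnea–hypopnea index: non-OSA below 10
events/h, OSA above 15; the intermediate 10–15 band is excluded from
training and evaluated separately as a borderline phenotype group.

Because the clinical audio is not publicly deposited, the package ships a
first-class synthetic cohort generator that reproduces the statistical
structure the pipeline assumes, so every stage — and the framework
end-to-end — is testable from a seed.

## Signal path

Each subject contributes two recordings (nose route, mouth route), each
beginning with a breath-hold *silent period* followed by five deep
breathing cycles. The per-recording processing is:

1. **Envelope segmentation.** The log variance in 30 ms windows with 50%
   overlap forms the envelope. The detection threshold is the midpoint
   (in log-variance units) between the median envelope of the silent span
   and the recording's 95th-percentile envelope; contiguous
   supra-threshold runs longer than 250 ms become phases, labeled by
   alternation starting with inspiration (deep-breathing protocols begin
   with an inhalation). The threshold rule and minimum duration are
   package choices; the 250 ms floor rejects clicks.
2. **SNR gating.** Per-phase SNR is the linear power ratio of the phase
   to the silent period, computed on the raw (pre-decimation) signal.
   Phases below 2 (≈3 dB) are dropped; a subject is excluded when any of
   the four maneuvers (MI, ME, NI, NE) retains fewer than two phases.
   Adjacency to the silent period is recorded but does not by itself drop
   a phase — the SNR rule is the operative filter.
3. **Conditioning.** Zero-phase Butterworth band-pass 75–5000 Hz
   (order 4) as anti-aliasing, decimation ×4 (44.1 kHz → 11025 Hz), then
   extraction of the *stationary portion*: 50% of the phase duration
   centered on the envelope maximum (ties to the earliest frame; the
   window shifts inward at edges). The stationary segment is band-passed
   75–3500 Hz (order 6), smoothed with an 8-sample centered moving
   average (intra-segment variation), and divided by its standard
   deviation (inter-segment variation), leaving unit variance. Band-pass
   filters are realized as cascaded high-pass and low-pass sections,
   which is numerically robust at the very small normalized corner
   frequency (75 Hz at 44.1 kHz); filtering is forward–backward so the
   envelope timing used by segmentation is preserved.

## Acoustic features

Each conditioned segment is decomposed with a 5-level Symlet-8 wavelet
packet transform into 32 terminal sub-bands, reordered from tree order to
frequency order by the binary-reflected Gray code (packet terminal nodes
are not frequency ordered naturally, because the high-pass branch folds
the spectrum). At 11025 Hz the nominal band width is
`11025 / 64 = 172.27` Hz, and the first 10 bands (up to 1722 Hz) are kept
— breath-sound energy above ~2 kHz is minimal at these SNRs.

Boundary handling is **periodized**, making the transform exactly
orthogonal: the sum of squared coefficients over the 32 bands equals the
squared norm of the (trimmed) input to machine precision. This property
is tested, and it is the reason periodization was preferred over
symmetric extension, whose redundant boundary coefficients break energy
accounting; inputs are trimmed to a multiple of 32 samples, a negligible
loss at segment lengths of thousands of samples.

Sixteen descriptors per band (statistical: mean, variance, sd, energy,
median; higher-order: skewness, kurtosis; temporal: zero-crossing rate;
spectral: centroid, spread, skewness, kurtosis, entropy of the
normalized coefficient periodogram; complexity: Shannon, Tsallis(q = 2),
Rényi(α = 2) entropies of the normalized squared coefficients) give
160 features per cycle, averaged over a maneuver's cycles, and the four
maneuver blocks concatenate to the 640-dimensional acoustic vector.
The flat index is `(maneuver − 1)·160 + (band − 1)·16 + descriptor` with
maneuvers ordered MI, ME, NI, NE. Entropy orders 2 are package defaults
(closed forms at uniformity make them easy to verify); spectral
descriptors are computed on the coefficient periodogram by default, with
the band-limited reconstruction exposed as a config switch. Sample
(n − 1) standard deviations are used throughout. Zero-energy bands
return 0 for the otherwise undefined descriptors rather than NaN.

Features are z-scored with statistics fitted on the *training* subjects
only and applied to held-out subjects — fitting on everyone would leak
the test distribution into the scaler. Subjects missing a whole maneuver
are dropped from training; at prediction their missing block is imputed
at the training mean (0 after scaling) and flagged.

## Feature selection

Within each sub-classifier's training data, `B = 1000` balanced subsets
are drawn: all minority-class subjects plus an equal-size draw (without
replacement, independent across subsets) of the majority. On each
subset, greedy mRMR selects up to 7 features: step one maximizes the
mutual information `I(f; y)`; step `t` maximizes
`I(f; y) − |S|^{-1} Σ_{s∈S} I(f; s)`, stopping early when the best step
score falls below 0.01. Mutual information is the plug-in estimate after
discretizing each feature into 3 bins at mean ± 0.5 sd (the classic mRMR
scheme; the set-level objective normalizes redundancy by `|S|^{-2}` and
is available via `redundancy_exponent = 2`, but the greedy difference
form is the default). Ties resolve to the smaller feature index
everywhere, making selection deterministic.

Selection frequency over the `B` subsets is the stability score; the
top 7 per inner split form a candidate set, candidate sets are pooled
over all inner folds and repeats, and the 7 features with the highest
recurrence are the sub-classifier's final acoustic features, joined by
the three anthropometric features to a 10-dimensional input.

A property worth knowing: because every subset contains the *full*
minority class, stability frequencies are correlated across subsets — on
null data a chance association can recur at high frequency within one
labeling. Exchangeability shows up across label permutations instead
(the identity of the top feature is unstable), which is how the test
suite probes the null behavior.

## Ensemble training and fusion

Per sub-classifier, `Nmin = ceil(n_majority / n_minority)` balanced
subsets suffice to cover every majority subject; `M = 3·Nmin` trees are
grown, with majority draws forming a shuffled partition within each
block of `Nmin` subsets (the last subset of a block is padded by
resampling already-used indices), so coverage holds per block. Each
decision tree (`rpart`, probability leaves, `cp = 0`) is trained on one
subset; tree depth {3, 5, unlimited} × minimum leaf size {1, 3, 5} are
tuned by balanced accuracy of the probability-averaged predictions on
the inner validation folds. The inner fold count is
`clamp(floor(n_minority/3), 3, 6)` with 5 repeats by default — more
folds only when the subgroup's minority class can support them; below 3
minority subjects a single split is used and flagged.

The sub-classifier probability is the plain mean of its trees' OSA leaf
probabilities; the final probability is the unweighted mean over `Kx`
(equal weights regardless of subgroup training size). A majority-voting
mode is provided for comparison; its 2–2 tie with `|Kx| = 4` resolves to
OSA, since in screening a false negative costs more than a false
positive. Sub-classifiers that are untrainable in a fold (a class absent
from the subgroup's training data) are excluded from `Kx` at prediction.

## Evaluation harness

Outer evaluation is stratified 4-fold cross-validation on the binary
population: per-fold accuracy, sensitivity, specificity, balanced
accuracy (their mean), and rank-based AUC (concordance with half credit
for ties, pooled per fold); pooled confusion matrix across folds; a
decision-threshold sweep over 0.40–0.60; leave-one-subgroup-out fusion
(recompute `p_final` with one sub-classifier removed; subjects left with
no member — possible only when some subgroups are untrainable — are
dropped from that row); and the intermediate-AHI group predicted by each
fold's model, reported as the fraction labeled OSA. A *global baseline*
runs a single non-stratified bagged-trees ensemble on the identical
folds; by default its trees use ordinary bootstrap samples, the standard
bagging comparator whose majority-class collapse on imbalanced data is
the failure mode the stratified design exists to avoid (a balanced
variant is available via `balanced = TRUE`). Reported percentages are
rounded half-up to one decimal.

## The synthetic cohort generator

`generate_cohort()` draws per-class anthropometrics with the cohort
structure the framework assumes: OSA prevalence of male sex, higher age,
BMI, Mallampati grade, neck circumference and snoring; AHI from
class-conditional truncated normals (OSA 42.6 ± 26.7 truncated above 15;
non-OSA 5.7 ± 2.6 within [0, 10); intermediate uniform on [10, 15]).
For the continuous strata the stratum side (e.g. BMI > 35) is drawn
first at the target subgroup proportion and the value then drawn from
the class-conditional normal truncated to that side — this pins the
subgroup marginals while keeping the class means, which a plain normal
draw cannot do simultaneously. `null_anthro = TRUE` pools the two
classes' distributions for null experiments.

`synthesize_recording()` emits one mono recording per subject per route:
a stationary Gaussian noise floor, a leading breath-hold, and five
(configurable) inspiration/expiration cycles. Each phase is Gaussian
noise spectrally shaped (FFT-domain gains over the 10 analysis bands,
gentle base decay of −1.5 dB/band) and enveloped with a raised-cosine
(Tukey) window — sustained mid-phase airflow with cosine onset/offset
ramps, which is both the physiological shape of deep breathing and what
makes the envelope detector's task realistic. Per-subject band gains
jitter with sd 2 dB; *spectral signatures* shift a chosen band's
log-energy for matching subjects (class and/or subgroup and/or maneuver)
in units of that 2 dB sd. Intermediate-AHI subjects receive half of any
class-targeted effect, placing them acoustically between the classes.
Per-phase duration and gains jitter with a 10% coefficient of variation
so cycle averaging is non-trivial.

The dataset-level SNR target (10.7 ± 4.2 dB) is decomposed into a
between-recording component and a 1.5 dB within-recording component:
microphone fit and breathing effort dominate the spread in practice, and
a per-recording level is also what makes a per-recording detection
threshold meaningful. Planted SNR is the linear power ratio of the whole
phase (signal plus floor) to the floor — the same quantity the gating
rule thresholds.

What the generator does *not* emulate: physically realistic airway
acoustics, room reverberation, and non-stationary artifacts (speech,
hammering). Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers structure *of the kind it assumes*, not
clinical performance; the signature effect sizes are free parameters
(default 1 sd) because the two classes' real spectra overlap too heavily
to calibrate them from published summaries.

## Problem sizes used by the tests and the acceptance script

Module tests synthesize audio at 8 kHz with proportionally scaled filter
bands, which exercises the identical code path at a fraction of the
cost. The packaged end-to-end study uses 96 subjects at the study's
class proportions (63 OSA / 20 non-OSA / 13 intermediate), 2 cycles per
maneuver, `B = 200`, 2 inner repeats, and full-rate 44.1 kHz audio —
sizes chosen so a complete run takes a few minutes on one CPU while every
stage still has enough data to train. The stability-recovery simulation
uses a 300/100 cohort so each balanced subset carries 200 samples, the
regime where the 3-bin plug-in MI estimator reliably separates a 1-sd
effect from the maximum over 637 noise features; at the study's own
149/47 marginals the planted features still enter the top 7, but their
selection frequency is estimator-limited rather than method-limited.
The null-cohort experiment repeats a 24-subject balanced cohort over 20
seeds and checks that the cross-validated balanced accuracy's 95%
confidence interval covers 50%.

## Numerical choices and degenerate inputs

* Log-variance epsilon floor: `1e-12 ×` the mean signal power (with an
  absolute floor), so silent windows yield a finite constant envelope.
* Argmax ties (envelope peak, mRMR scores, consensus ranking): earliest
  frame / smallest index, for determinism.
* Zero-variance feature columns: scaler sd replaced by 1 with a warning.
* Zero-energy wavelet bands: descriptor sentinels of 0, never NaN.
* Zero silent-period power or zero-variance segments: explicit errors —
  these indicate degenerate inputs upstream, not conditions to paper
  over.
* All randomness derives from one integer seed through a string-hash
  fan-out (`derive_seed`), so every stage, subgroup, fold and tree can be
  re-run bit-identically from the manifest.

## Known limitations

* Decision trees come from `rpart`; exotic hyperparameters of other tree
  implementations are out of scope.
* The intermediate-AHI group's synthetic phenotype (half-effect
  signatures, averaged anthropometrics) is an assumption, not an
  estimate; its predicted-OSA fraction on synthetic data should not be
  read as a clinical expectation.
* The harmonic-comb detector is a screening heuristic replacing a manual
  spectral review; it flags strong periodic interference and nothing
  subtler.
* Probabilities are not calibrated; fusion weights are equal by design.
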