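---
title: "scdEEG: models, assumptions and design choices"
author: "scdEEG maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scdEEG: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package computes

`scdEEG` implements the quantitative core of an amyloid-stratified
resting-state EEG study in subjective cognitive decline (SCD): subjects with
normal neuropsychological performance but subjective complaints are split by
amyloid-PET status into a small positive (A+) and a larger negative (A-)
group, and the question is whether 19-channel eyes-closed EEG carries enough
signal to separate the groups and to track severity. The analysis chain is

1. **Preprocessing** — zero-phase 1–55 Hz band-pass, segmentation into 2-s
   epochs, peak-to-peak artifact rejection at 150 µV, and random selection
   of 60 artifact-free epochs per subject.
2. **Spectral features** — Welch power spectra (each 2-s epoch is one
   Hamming-windowed segment; 0.5 Hz resolution) reduced to relative power in
   delta (1–4), theta (4–8), alpha (8–12), beta (12–30) and gamma
   (30–55 Hz), per channel plus a `Global` channel mean, in percent of the
   1–55 Hz total.
3. **Connectivity** — weighted phase-lag index (wPLI) per band:
   `|E Im S_xy| / E |Im S_xy|` across the 60-epoch ensemble, averaged over
   the band's frequency bins. Because only the imaginary cross-spectrum
   enters, instantaneous (volume-conduction) mixing contributes nothing.
4. **Graph metrics** — proportional thresholding (keep the strongest 5–35 %
   of edges, in 5 % steps), then weighted clustering coefficient (Onnela
   geometric-mean-triangle form, weights normalised by the matrix maximum),
   node strength, and global efficiency (mean inverse weighted shortest
   path, edge length `1/w`), each averaged across the seven thresholds.
5. **Statistics** — moment-based normality screen (|skewness| < 2,
   |excess kurtosis| < 7), pooled-variance t tests with pooled-SD Cohen's d,
   chi-square tests, ANCOVA with age as covariate and partial eta squared,
   and age-adjusted partial correlations with a 5000-replicate bootstrap CI.
6. **Classification** — AdaBoost over depth-1 decision stumps (50 rounds,
   learning rate 1, no tuning), greedy sequential forward selection capped
   at 20 features, stratified 10-fold cross-validation with fold-wise
   z-scoring and Borderline-SMOTE applied to training folds only,
   label-permutation significance, and exact Shapley attributions.

Because no public recording set exists for this design, the package carries
a first-class synthetic-cohort generator whose defaults emulate the study's
statistical structure; every stage above is exercised end-to-end on it.

# The synthetic cohort generator

`cohortSpec()` fixes the study conditions: 24 A+ and 82 A- subjects, 180 s
of 19-channel EEG each, A+ older on average (73.4 vs 69.8 years), APOE4
carrier rates 50 % vs 11 %, and four cognitive percentile scores tied to a
latent severity.

Each recording is synthesised in the frequency domain as a sum of

* five band-limited stochastic sources with per-band RMS amplitudes
  (delta 3.3, theta 2.7, alpha 4.9, beta 3.6, gamma 0.4 uV) and a scalp
  topography (posterior-dominant alpha, frontal-leaning delta). The
  amplitudes were solved jointly with the background so that baseline
  relative powers sit at realistic eyes-closed values (delta ≈ 23 %,
  alpha ≈ 30 % globally, ≈ 47 % at O1);
* a `1/f` background (RMS 5.3 µV over 1–55 Hz), which alone reproduces a
  log-log PSD slope of −1;
* white sensor noise (RMS 1.3 µV);
* shared narrowband sources for phase coupling: member channels mix a
  common source with channel-specific delays (integer samples, a documented
  approximation of constant phase lag) at strength `rho`, blended as
  `sqrt(1 - rho^2)·own + rho·shared` so variance is strength-invariant.
  Defaults couple the posterior channels in alpha (10 ms lag) and the
  frontal channels in delta (16 ms).

A latent **severity** (A+ ~ N(2.2, 1.0), A- ~ N(1.2, 1.0), clipped to
[0, 4.5]) scales a single *pathology profile* shared by every subject —
delta 1.26, theta 1.27, alpha 0.905, beta 0.985 amplitude multipliers at
unit severity — so the groups differ only through their severity
distributions. The same latent depresses the cognitive percentile scores
(`72 − 15·severity + N(0, 5)`, clipped to [0, 100]). One mechanism
therefore plants the delta/theta-up, alpha-down group signature, the group
score gap, and the negative theta-score / positive alpha-score
correlations at once; crucially, because severity varies widely *within*
groups, the severity-EEG-score correlations are recoverable across the
whole cohort, not just as a group contrast.

Three presets exist. `"paper"` is the default; its pathology profile,
severity spread and coupling strengths (alpha 0.46 vs 0.53, delta 0.38 vs
0.32) were calibrated jointly so that (a) ANCOVA partial eta squared on
the affected features lands around 0.04–0.10 — the range the motivating
cohort reports — and (b) the age-adjusted partial correlation between
global theta power and a memory score is significantly negative in the
large majority of simulated cohorts; both targets are part of the design,
and the calibration was then frozen. These two targets pull against each
other (a fixed group effect bounds the cohort-wide correlation unless
within-group severity variance is large), which is why the severity SD is
deliberately wide relative to the group gap of 1. A further subtlety shaped
the calibration: because relative powers are shares of a common total,
delta and theta gains compete through the denominator, so their slopes are
kept comparable (and alpha/beta absorb most of the counter-movement) —
otherwise whichever band dominates a given cohort suppresses the other's
relative-power group difference.
`"strong"` makes the groups nearly separable (profiles 2.5/1.9/0.4
applied to A+ only, severity SDs 0.1) and is the right input for
validating the classification framework on planted signal. `"null"`
removes every group difference and underpins calibration tests.

Artifacts are injected as 0.3-s half-sine transients (default 400 µV,
2 events/min, Poisson-timed on random channels) with a retained event log,
so amplitude-based rejection has something real to reject.

**What the generator does not emulate:** head-model/leadfield mixing (beyond
the instantaneous-mixing invariance checks), eye-blink or EMG morphology,
non-stationarity across the recording, reference-scheme effects, and any
true neurophysiology of amyloid. Passing tests therefore demonstrate that
the pipeline recovers effects of the planted kind at realistic sizes — not
that it would classify a clinical cohort at any particular accuracy.

# Numerical and design choices

**Band-pass response.** Filtering is a zero-phase frequency-domain
band-pass: unit gain on [1, 55] Hz with raised-cosine transitions of 0.5 Hz
and zero gain beyond. Exactly zero phase is non-negotiable for wPLI. A
conventional low-order forward-backward Butterworth was rejected because
its transition at a 55 Hz edge is far too shallow to suppress 60 Hz mains
(≈ 12 dB); the implemented response removes DC and mains essentially
completely while leaving 10 Hz untouched (< 0.01 dB). Circular edge effects
of FFT filtering are negligible on 3-minute records.

**Sampling rate.** The acquisition hardware's rate is a free parameter; the
package default is 250 Hz. Bulk simulation suites (the 20-cohort
directional-recovery run, the planted-signal classification run) use
128 Hz — the analysis range only requires Nyquist > 55 Hz and the 0.5 Hz
Welch resolution is set by the 2-s epoch, not the rate; this is the problem
size chosen for those studies.

**Welch conventions.** One segment per epoch, no overlap, Hamming window
with window-power normalisation; `sum(psd·df)` matches signal variance
(Parseval) within Monte-Carlo error. Band edges are half-open `[lo, hi)`
with 55 Hz inclusive in gamma, so bins are never double-counted and the
five relative powers sum to exactly 100 per location.

**wPLI estimator bias.** The plain wPLI estimator is used (the study names
the plain variant; the debiased square estimator is deliberately not
substituted). Its finite-sample null level is not zero:
`E[wPLI] ≈ sqrt(2/(pi·n))·sqrt(2) ≈ 0.146` at n = 60 epochs, and
single narrow-band pairs fluctuate up to ≈ 0.3. Tests and acceptance
checks therefore assert the matrix-mean null level (< 0.2) and a
finite-sample per-pair bound (< 0.35), not per-pair near-zero values;
coupled pairs at quarter-period lag reach ≥ 0.9 and instantaneous mixing
stays at the null level.

**Thresholding and tie-breaks.** `round(p·n(n−1)/2)` strongest edges are
kept, ties resolved by first occurrence in row-major upper-triangle order
via a stable radix sort, so results are bit-reproducible. Thresholded
matrices keep their weights (weighted, not binarised, metrics). The seven
threshold values are aggregated by unweighted mean; a per-threshold output
remains available through `networkFeatureVector(..., thresholds = p)`.
Global efficiency is exactly non-decreasing in the threshold proportion;
weighted clustering is not guaranteed monotone (weak edges raise binary
degrees faster than triangle mass) — the test suite counts violations
rather than hiding them.

**Statistics conventions.** Pooled-variance t and pooled-SD d reproduce the
printed effect sizes of the motivating study's cognitive table to two
decimals; the d CI uses the large-sample standard error
`sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2)))`. The kurtosis screen uses excess
kurtosis. ANCOVA partial eta squared is `SS_group/(SS_group + SS_residual)`
from an extra-sum-of-squares comparison, order-independent for the
two-term model. Partial correlations are Pearson correlations of
least-squares residuals with `t = r·sqrt((n−3)/(1−r²))` on n − 3 df and a
percentile bootstrap CI over subject resamples. No multiple-comparison
correction is applied by default, mirroring the exploratory convention of
the motivating analyses; `groupComparisonReport(..., fdr = TRUE)` adds a
Benjamini–Hochberg column.

**Classifier pinning.** Discrete AdaBoost, depth-1 stumps, 50 rounds,
learning rate 1; stump search is exact over midpoint thresholds with
deterministic tie-breaking (first feature, smallest threshold), margins at
exactly 0 resolve to the negative class. The selection objective is pooled
CV accuracy with MCC and then column order as tie-breaks, and the returned
set is the best-scoring prefix of the greedy path. Inside `sfsSelect()`,
fold-wise scaling and Borderline-SMOTE are computed once per fold in the
full feature space and candidate subsets index that augmented set — every
candidate is compared on identical folds and augmentation, at a large
speed gain; the final `cvEvaluate()` re-runs SMOTE on the selected subset
only. Subjects are sorted by identifier before fold assignment, making
results invariant to input row order.

**Non-nested default, nested check.** By default selection is performed
once on the full table and then cross-validated — the design whose
optimism the motivating study itself acknowledges; `nestedCvEvaluate()`
re-runs scaling, oversampling and selection inside every outer fold and is
the leakage-free variant used to verify that pure-noise features score a
mean MCC within ±0.1 of zero. Permutation p-values use
`(1 + #{permuted ≥ observed})/(B + 1)`; the full per-shuffle evaluation
(folds, scaling, SMOTE, training) is re-run, while re-running selection
itself is available via `refitSelection = TRUE` and is intended for
reduced B — at B = 5000 and 306 features it is computationally out of
reach, which is why it is not the default.

**SMOTE details.** Borderline-1 with k = 5 for both danger detection and
synthesis; minority points whose neighbourhoods are entirely majority are
noise and never seed synthesis. Training folds whose minority class is
smaller than k + 1 are left unbalanced with a warning rather than
synthesised from degenerate neighbourhoods.

**SHAP.** For stump ensembles the margin is additive across features, so
Shapley values are exact and cheap: a feature's attribution is the summed
vote of its stumps centred on the background mean. Additivity
(`base + Σφ = margin`) holds to machine precision; a constant feature
receives exactly zero.

# Degenerate inputs and errors

Insufficient clean epochs raise an error naming the subject; the pipeline
records such subjects in its manifest and continues while at least four
subjects per group survive. Zero-variance samples, zero pooled variance,
collinear ANCOVA covariates, empty bands, out-of-range threshold
proportions, single-epoch wPLI and sub-k SMOTE minorities all raise
explicit errors (or documented warnings) rather than propagating NaN.

# Problem sizes used by the validation suites

The shipped test and acceptance runs use: full 24 + 82 cohorts of 180-s
recordings at 128 Hz for the directional-recovery (20 seeded cohorts) and
planted-signal classification studies; 60-epoch ensembles for all wPLI
properties; 5000 simulations for t-test type-I calibration; 150
simulations × 200 bootstrap replicates for CI coverage; exhaustive
enumeration of all graphs on up to 6 nodes plus 200 random graphs (n ≤ 8)
for the graph-metric oracles; and B = 200 permutations for classifier
significance. The reported permutation floor at B = 5000 (≈ 0.0002) is
documented by formula rather than re-simulated.

# Known limitations

* The generator's effects are stationary, Gaussian and linear; real EEG is
  none of these.
* The artifact model exercises amplitude-threshold rejection only; the
  multi-stage cleaning chains used on clinical data (line-noise regression,
  subspace reconstruction, component classification) are out of scope, and
  a pre-cleaned recording can be supplied to the pipeline instead.
* Absolute classifier metrics on synthetic cohorts reflect the planted
  separability, not clinical performance.
* EDF support covers the 16-bit continuous single-rate layout this package
  writes; it is not a general EDF+ reader.
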