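---
title: "Methods: windowed seizure detection with interpretable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed seizure detection with interpretable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The detection problem

Electrographic seizures are rare, high-amplitude, rhythmic episodes
embedded in many hours of background EEG/LFP. Manual review is the de
facto standard and is slow and inconsistent, so `seizr` implements a
semi-automated design: a deliberately *sensitive* classifier proposes
candidate events, and a human reviewer accepts or rejects them. The unit
of classification is a 5-second window; everything downstream (training,
metrics, events) is defined on windows.

The pipeline is:

1. **Preprocess** — zero-phase high-pass, antialiased downsampling,
   segmentation into 5-s windows, outlier repair.
2. **Features** — a small battery of per-window statistics per channel
   (line length, RMS, mean absolute deviation, variance, SD, band power,
   energy, Hilbert-envelope amplitude, lag-1 autocorrelation) plus
   zero-lag correlation/covariance for channel pairs; all z-scored.
3. **Selection** — drop features correlated above a threshold, then rank
   the survivors by one-way ANOVA F or mutual information with the label.
4. **Models** — Gaussian naive Bayes (GNB), CART decision tree, an SGD
   linear model (logistic or hinge loss), or a passive-aggressive
   classifier; tuned by grid search on balanced accuracy under stratified
   4-fold cross-validation, then trained as 5 replicates on distinct
   stratified 80% subsets.
5. **Events and metrics** — runs of at least two consecutive predicted
   windows become seizure events; scoring is both window-level (recall,
   precision, specificity, F1, balanced accuracy) and event-level
   (percent of seizures detected; false detections per hour).

# Preprocessing choices

**Order of operations** is high-pass → downsample → segment → repair.
The high-pass (2nd-order Butterworth, 2 Hz for LFP work, 0.5 Hz for
scalp EEG) runs at the native rate so drift is removed before any
decimation; the antialias stage is a zero-phase FIR low-pass at
0.4 × target rate followed by decimation (polyphase resampling when the
ratio is not an integer).

**Edge transients.** Zero-phase filtering is applied with odd
end-reflection padding (three filter time-constants for the IIR
high-pass, three filter lengths for the FIR). Without padding, the
forward–backward pass leaves a visible transient at both ends of the
recording — a constant input would not even come out as zero.

**Outlier repair.** Samples further than `outlier_sd` (default 25)
standard deviations from the channel mean are replaced by the median of
their 5-second window. The detection reference is deliberately
*recording-wide*: within a 500-sample window, a lone spike inflates the
window's own SD so much that the within-window |z| can never exceed
√500 ≈ 22.4, and a per-window 25-SD rule would never fire on exactly the
artifacts it exists for. The replacement value remains local (the window
median), which confines the correction to the corrupted window.

# Feature definitions and normalization

Feature formulas are fixed by this package (window `x`, `n` samples):
line length `Σ|xᵢ−xᵢ₋₁|`; RMS `√mean(x²)`; MAD `mean|x−x̄|`;
population variance/SD; energy `Σx²`; envelope amplitude = mean
magnitude of the FFT-computed analytic signal; autocorrelation is the
*unnormalized* lag-1 sum `Σxᵢxᵢ₊₁` (in that form it is genuinely
redundant with energy, which is why the scalp configuration drops it);
band power integrates the single-window periodogram over each band,
scaled so the positive-frequency bins sum to the window variance
(Parseval). Welch averaging is pointless at 500 samples per window, so
the plain periodogram is used. The 2-channel LFP configuration uses one
broad 2–40 Hz band and three cross-channel features on the single pair
(21 columns); the 18-channel scalp configuration splits power into five
bands (1–4, 4.2–8, 8.2–12, 12.2–30, 30.2–55 Hz), drops autocorrelation
and all cross-channel features (216 columns), and keeps the native
256 Hz rate so the gamma band stays below Nyquist.

Z-score constants (per-feature mean/SD) are always fitted on training
windows only and applied frozen to validation and test matrices; a
zero-SD feature maps to an all-zero column with a warning rather than
NaNs.

# Selection, tuning, replication

Correlation pruning is a greedy keep-first scan in column order
(deterministic, order-stable, idempotent); thresholds default to 0.99
(LFP) and 0.90 (scalp). Ranking is applied to the *pruned* set. The
ANOVA score is the vectorized two-group F statistic; mutual information
uses a nearest-neighbour estimator for the continuous-feature /
binary-label case (k = 3), with a plug-in histogram estimator as the
independent oracle in tests. Ties rank by original column order;
zero-variance features rank last. In the multi-subject harnesses the
selection is re-fitted inside every training fold.

Tuning maximizes mean balanced accuracy over a stratified 4-fold split
(75/25), ties broken by grid order; a fold that loses the minority class
is an error, not a silent skip. Final training produces 5 replicate
models on the complements of 5 stratified folds (80% each). All
randomness (fold deals, SGD/PAC shuffles, the generator) derives child
seeds from one root seed.

The SGD and passive-aggressive fits use per-sample updates with the
standard inverse-time learning-rate schedule (SGD) / PA-I updates (PAC),
and return the average of the iterates over the final epoch. Averaging
is what makes the learned direction stable enough to be interpreted —
the final iterate alone wobbles with the last few samples seen.

Class imbalance is handled two ways, matching the scalp-EEG workflow:
balanced accuracy as the fit metric, and optional sliding-window
upsampling of seizure spans at 0.5-s offsets. Upsampled windows are cut
from the continuous filtered signal (not jittered copies), skip offsets
that coincide with the base grid, and are only ever added to training
folds.

# Events, matching and conventions

Predicted events are maximal runs of ≥ 2 consecutive positive windows;
ground-truth events count at any length. A true event is *detected* if
at least one predicted event shares ≥ 1 window with it; a predicted
event is *correct* under the same overlap rule. The false detection rate
is (predicted − correct-predicted) events per hour, which is
non-negative by construction even when several predictions land inside
one long seizure. Zero-denominator rates are reported as 0 and flagged
(rather than NaN) so aggregate tables stay numeric; percent detected is
100 when there are no true events.

# What the synthetic generator emulates

The generator plants amplitude-modulated oscillations (5–15 Hz carrier,
trapezoidal envelope, cross-channel correlation 0.8) into 1/f background
noise. Defaults are 2 channels at 400 Hz for 9000 s with 24 seizures of
20–40 s and `ictal_gain = 5`; the injected amplitude is
`(ictal_gain − 1) × background SD`, so gain 1 is an exact null
configuration. The 1/f background makes the high-pass stage
consequential; the trapezoidal envelope makes boundary windows genuinely
harder than event centers, reproducing the qualitative
center-versus-boundary detection asymmetry. The 400 Hz native rate keeps
the antialiasing path exercised while staying far above the 40 Hz
analysis band; the 9000-s duration gives ≈ 8% seizure windows — easier
than chronic-monitoring imbalance, but enough background (2.5 h) for a
meaningful false-detections-per-hour scale.

What it does **not** emulate: spike-wave morphology, post-ictal
suppression, movement/electrode artifacts, non-stationary background
state changes, or realistic seizure rarity. Passing the end-to-end
checks therefore demonstrates that the pipeline's plumbing, leakage
discipline and event logic are correct and that the features separate
amplitude/rhythmicity changes as intended — not that any particular
performance level transfers to real recordings.

# Validation problem sizes

The test suite validates feature formulas and metrics against
brute-force oracles (1000 random confusion tables and run-length
vectors), checks GNB against an independent naive-Bayes implementation,
and runs the full pipeline end-to-end on a train/test pair of generator
recordings at the default conditions above (1800 windows each), where
both the GNB and SGD pipelines detect 24/24 planted seizures with zero
false events, and GNB keeps 100% detection from a 1% training fraction
(18 windows) upward. Multi-subject schemes are exercised on
Gaussian-feature subjects (24 subjects for the 18/6 inter-subject
layout) with per-fold provenance asserting that normalization, selection
and tuning never saw a test window.

# Known limitations

Five-second windows cannot localize seizure onset/offset precisely;
downsampling to 100 Hz discards high-frequency content; the review stage
is a text prompt, not a trace viewer; and the four model families are
linear or axis-aligned — deliberately so, since the design goal is
interpretability (Gini importances, weight magnitudes, and the GNB
separation score `|μ₁−μ₀|/(σ₁+σ₀)`, each normalized to sum to 1).
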