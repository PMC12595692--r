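---
title: "Methods: predicting muscle response to FES therapy from baseline sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting muscle response to FES therapy from baseline sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesresponder)
```

## The problem and the model

After cervical spinal cord injury (SCI), functional electrical stimulation
(FES) therapy can improve upper-extremity strength, but individual muscles
respond very unevenly: injury level, preserved fibers, and lower-motor-neuron
integrity all differ across muscles and patients. The question this package
operationalises is whether a single pre-therapy surface EMG (sEMG) recording
session per target muscle carries enough information to predict, at the
muscle level, who will benefit.

The pipeline has three statistical components:

1. an **outcome definition** mapping a longitudinal ordinal strength
   trajectory to a binary responder label,
2. a **feature bank** summarising a voluntary-contraction sEMG segment, and
3. an **evaluation harness** measuring out-of-participant predictive skill
   under severe class imbalance.

## Responder labeling

Manual muscle testing (MMT) assigns each muscle an ordinal grade 0–5 before
each therapy session. A muscle is a *responder* when its scores show a
statistically reliable positive monotone association with session number:
Kendall's τ > 0 with p < α, α = 0.01. A positive τ necessarily implies at
least one ≥ 1-grade increase, and a trend statistic is far more stable than
a first-versus-last comparison under rater noise.

Design choices the rule itself leaves open:

* **Tau variant.** MMT scores are heavily tied, so we use the tie-corrected
  τ-b (`stats::cor(..., method = "kendall")`). With τ-a, long runs of tied
  scores would deflate the coefficient toward zero for purely combinatorial
  reasons.
* **P-value.** Two-sided, with the positive direction enforced separately by
  the τ > 0 condition. For 10 or more sessions we use the normal
  approximation with the full tie-corrected variance of the S statistic
  (base R's `cor.test()` does not tie-correct the variance, so this is
  implemented in the package and checked against exact enumeration).
  Below 10 sessions the package enumerates all score permutations exactly.
* **Degenerate trajectories.** An all-tied (constant) trajectory has no
  defined rank correlation; we define τ = 0, p = 1, i.e. non-responder.
* **Ceiling.** Muscles at grade 5 at baseline cannot improve on the scale
  and are excluded before labeling.

## Signal preprocessing

Clinical acquisition applies a 20–450 Hz hardware bandpass; the package
re-applies it in software (4th-order Butterworth overall, zero-phase
forward–backward) so that the pipeline is self-contained on synthetic or
unfiltered inputs, followed by a single second-order IIR notch at 60 Hz
with Q = 30. Zero-phase IIR filtering leaves start/end transients — the
notch impulse response lasts ~0.5 s — so both filters run on an
odd-symmetric reflect-padded copy of the signal (1 s each side) and the
padding is trimmed afterwards. The output is re-centred, making the
post-condition mean ≡ 0 exact.

Feature extraction consumes one 3-s **steady-state segment** per MVC trial:
the window with the lowest sample standard deviation, searched at a 0.05 s
stride (near-exhaustive at a fraction of the cost; the rolling SD uses
cumulative sums). Ties are broken by the earliest start. The SD is computed
on the filtered signal — the same samples the features see.

## The feature bank

The 24 features follow the myoelectric-control literature. Conventions that
needed fixing:

* **Dead zone.** ZERC, SSC and wAmp share one threshold (default 10 µV)
  so baseline noise does not register as activity; counts are monotonically
  non-increasing in the threshold (a tested invariant).
* **Variance family.** VAR is the mean-subtracted N−1 variance; DVARV uses
  N−2 over first differences; M2 = Σ(Δx)² exactly, so M2 = (N−2)·DVARV is
  an algebraic identity the tests assert.
* **logD** guards log(0) with a configurable floor (10⁻¹² mV).
* **Spectra.** Welch periodograms from 1024-sample Hann blocks at 50 %
  overlap (≈ 3.9 Hz resolution at 4 kHz); MeanF is the spectral centroid,
  MedF the half-power frequency. The Welch estimator is hand-implemented
  (no installed R routine provides it) and tested against a direct
  full-length periodogram oracle.
* **AR and cepstrum.** Yule–Walker AR(4) in the predictor convention
  x_t = Σ a_k·x_(t−k) + e_t. The cepstral coefficients come from the
  standard log-derivative recursion of the AR polynomial. Because the sign
  convention of that recursion is a frequent source of error, the
  implementation is verified against an independent spectral-path oracle:
  the inverse Fourier transform of the log AR model spectrum, agreeing to
  10⁻⁶.
* **EMGH.** Nine equal-width bins spanning ±3 SD around zero, counts
  normalised by N with out-of-range samples excluded (masses sum to ≤ 1);
  a zero-SD segment puts all mass in the centre bin by convention.
* **Card** counts distinct sample values identifying values within a
  tolerance: after sorting, a new value starts when a sample exceeds the
  last accepted value by more than the tolerance (so with tolerance 0.6,
  {0, 0.5, 1.0} has cardinality 2).

## Feature curation

Four curated sEMG sets plus a clinical set are built from the Full bank:
Hudgins (MAV, ZERC, SSC, wLen), MD (ZERC, SSC, wAmp, MedF, EMGH, ARCO3),
PCA (smallest number of components reaching 90 % of training variance,
z-scored by training statistics), and FWD (greedy forward selection).
Forward selection adds, at each step, the column maximising
leave-one-participant-out MCC *within the training partition*, stopping at
the first step with no strict improvement; ties break by column order. It
is run nested inside each outer cross-validation fold, so held-out
participants never influence the selected columns. The selection model
defaults to logistic regression for speed; any model factory can be
supplied. Clinical categorical variables (AIS, NLI, myotome) are encoded
ordinally (A<B<C<D, C2<…<C6, C5<…<C8) because responder prevalence trends
monotonically along both scales.

## Evaluation harness

Cross-validation is leave-one-participant-out (LOPO): all trials of one
participant form the test fold, preventing within-person leakage. All MVC
trials of a muscle are classified and the muscle's final label is the mode
of its trial votes; an exact tie resolves to non-responder, conservative
toward the majority class. Hyperparameter grids are deliberately small
(kNN: k = 2…7 × {euclidean, cosine}, distance-weighted; trees: 100 or 200
estimators; SVM: linear or gaussian kernel). The winning grid point is
chosen by nested LOPO MCC inside the training partition; a
`select_on_test` flag reproduces the optimistic variant that picks the
configuration on held-out performance, so both readings of an ambiguous
protocol are available, with the leakage-safe one as default. Features are
z-scored with training-fold statistics for distance/margin classifiers;
tree ensembles consume raw features. Kernel widths and tree depths stay at
library defaults and the chosen grid point is recorded per fold.

The AIS subgroup analysis re-runs the same harness restricted to the motor
complete (A–B) or motor incomplete (C–D) participants; `"A-D"` reduces to
the full run (a tested identity).

## Metrics

MCC is primary; accuracy, precision, recall, TNR and macro F1 (mean of the
per-class F1s) complete the suite, at overall, per-participant and
per-AIS-grade granularity. Every ratio with a zero denominator — including
MCC with a zero factor — is defined as 0, which is what per-participant
reporting requires when a participant has no responder muscles.

The **chance baseline** is formalised as a prevalence-matched independent
random predictor: with prevalence π, expected accuracy π² + (1−π)²,
precision = recall = π, TNR = 1−π, macro F1 = 0.5, MCC = 0 — the unique
model consistent with the whole published reference row. The
**confusion-matrix reconstruction** utility inverts a printed
(precision, recall, TNR) triple at 2 decimals into integer counts by
exhaustive search over TP and FP, erroring loudly on zero or multiple
solutions; printed values are compared after half-up rounding (base R
rounds half to even).

## The synthetic cohort

The study's clinical dataset is available only on request, so the package
generates cohorts with known ground truth. The generator emulates the
study conditions: 17 participants, AIS A/B/C/D = 2/5/2/8, NLI C2–C6 and
baseline MMT 0–4 drawn with the published frequencies, 4–10 target muscles
per participant with myotome at or below the injury level (distance 0–6),
one 60 s rest trial plus three 5 s MVC trials per muscle at 4 kHz, 30
sessions of MMT, and ~33 % responder prevalence rising monotonically from
AIS A to D.

The MVC signal model is **band-shaped Gaussian noise** (4th-order
Butterworth band, default width 120 Hz) scaled to an amplitude that grows
with baseline strength, plus white sensor noise (10 µV SD) and a 60 Hz
mains sinusoid (20 µV) — a deliberate stand-in for physiological
motor-unit activity that nevertheless drives every feature in the bank.
The responder effect is planted jointly in the spectrum (centre shifted up
by `effect_medf_shift`, default 30 Hz) and in amplitude
(`effect_amp_gain`, a multiplicative ratio, default 1.5), mirroring the
joint time/frequency character of the predictive features. These effect
sizes are configuration knobs for testing, not claims about real responder
physiology, which no public data describes. Trajectories are monotone
staircases gaining `responder_gain` grades (default 2, capped at 5) for
responders and flat for non-responders, both with ±1 MMT jitter at
probability 0.1 emulating inter-rater noise. Randomness is keyed by
(seed, participant, muscle, trial) through derived streams, so identical
configurations serialize byte-identically and sub-entities are
independently reproducible.

What the generator does **not** emulate: motor-unit recruitment and firing
statistics, fatigue within a trial, FES stimulation artifacts, electrode
placement variability, sex or age effects, or "discomplete" injury
phenomenology. Consequently, a high LOPO MCC on synthetic cohorts
demonstrates that the pipeline is correct and leakage-free — not that
real-data performance would match it.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for
desk-scale runs, as package choices: cohorts of 8–15 participants for
harness properties (a strong 60 Hz planted shift for the separability
check, 20 label permutations for the null), 200 trajectory replicates for
label recovery, and shortened rest trials where rest signals are unused
by the computation under test. The full 17-participant default remains the
generator's baseline configuration.

Other numerical conventions: Welch blocks shorter than the segment raise an
error rather than silently shrinking; the steady-state search always
includes the final window even when the stride overshoots; PCA drops
zero-variance columns with a warning; logistic fits under separation keep
finite predictions by thresholding the linear predictor at 0; collinear
logistic coefficients (NA) are treated as 0.

## Known limitations

* The published real-data headline results cannot be recomputed without the
  request-only clinical dataset; the acceptance surface covers the
  analytically reproducible quantities (chance row, reconstruction of the
  best-model and clinical-model rows) plus synthetic pipeline properties.
* Forward selection on trial-level rows evaluates its criterion on
  trial-aggregated muscle labels only at the harness level, not inside the
  greedy step, where trial-level MCC is used for speed.
* The exact permutation p-value is enumerated only below 10 sessions;
  beyond that the tie-corrected normal approximation is used.
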