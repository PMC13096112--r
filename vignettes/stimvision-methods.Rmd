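---
title: "Methods: kinematic scoring of DBS programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic scoring of DBS programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimvision)
```

This vignette documents the models, parameter choices and numerical
decisions behind `stimvision`, and the limits of what its synthetic
validation demonstrates.

## The problem

Modern multi-contact DBS electrodes give clinicians far more candidate
stimulation configurations than can be compared by eye. During a
programming session the patient performs repetitive hand opening–closing
under each candidate program and under stimulation-off; the package's job
is to turn those recordings into a defensible, patient-specific ranking of
the programs, and, at cohort level, into interpretable statements about
*which aspects of movement* a therapy improves.

The pipeline deliberately begins at the one-dimensional hand-aperture
signal (fingertip–wrist distance normalized by hand length). Video
processing and pose estimation live upstream and are out of scope; any
system that emits a uniformly sampled aperture trace, or directly a
feature table, can feed the scorer. Tremor-dominant phenotypes are out of
scope as well: oscillatory landmark displacement contaminates the aperture
signal, and no tremor decomposition is attempted.

## Cycle segmentation

Cycles are detected on a smoothed copy of the trace:

* **Smoothing** — zero-phase (forward–backward) 4th-order Butterworth
  low-pass at 8 Hz. The task band is roughly 0.5–4 Hz and the sampling
  rate 60 Hz, so 8 Hz preserves movement content while suppressing sample
  noise that would otherwise dominate the derivative-based features. The
  signal is extended by odd reflection (up to 1 s) before filtering so
  that filter start-up transients fall in discarded padding — without
  this, `signal::filtfilt`'s edge transients are large enough to fake
  oscillation on a flat trace.
* **Peak detection** — local maxima with prominence at least 20% of the
  trace's 5th–95th percentile range (absolute floor `1e-6` against
  numerically flat signals) and at least 0.2 s apart; ties resolve toward
  the earlier sample. Valleys are detected the same way on the negated
  signal, and the merged sequence is reduced to strict peak/valley
  alternation by keeping the more extreme member of any same-type run.
* **Boundary valleys** — a trace that starts or ends at valley level hides
  its outermost valleys at the signal edge. If the region outside the
  outermost peak reaches down to valley level, a valley is placed at the
  last (first) quiet sample before the rise (after the fall), so edge
  cycles are kept without absorbing leading or trailing rest. Degenerate
  edge cycles (opening or closing shorter than 15% of the median cycle
  duration, e.g. a recording cut right after a peak) are dropped.
* A cycle is a valley–peak–valley triple. Fewer than 2 cycles is an error
  naming the trace; fewer than 4 emits a warning.

Amplitudes are read off the *raw* samples at the detected indices: the
low-pass inevitably flattens sharp apexes, and measuring on the smoothed
curve would bias amplitude (and amplitude-decay) downward by several
percent. Velocities and accelerations come from central differences of
the smoothed signal.

## The 23-feature catalog

The catalog spans five families — amplitude, speed, rhythm, variability,
decrement — with per-feature orientation metadata (`higher_better` /
`lower_better`). Headline definitions: mean speed is the time-average of
|ds/dt| over the active task span; mean RMS velocity the root mean square
of ds/dt; opening/closing speeds the per-cycle peak |ds/dt| in each phase;
frequency the number of complete cycles divided by the time they span; and
every decay feature is the OLS slope of a per-cycle quantity against cycle
index, expressed as percent of the per-trace mean per cycle (which makes
decays invariant to amplitude rescaling). Decay and variability features
need at least 3 cycles and are reported as missing otherwise — never as
zero, which would masquerade as "no decrement".

The catalog is configuration, not code: the scoring machinery only consumes
orientations, so an alternative feature battery can be swapped in as a JSON
file without touching the scorer. Orientation defaults: amplitude, speed
and frequency features improve upward; durations, variability ratios,
hesitations and decay slopes improve downward.

## DWIS: dynamic weighting and shrinkage

Improvements are oriented percent changes against the patient's own
stimulation-off baseline. Cells whose baseline magnitude falls below
`1e-9` times the feature's column scale are masked rather than allowed to
explode, and a fully masked feature is flagged excluded. Percent change
(not raw difference) is used throughout, so the score is invariant to each
feature's units.

Responsiveness is the sample standard deviation (n−1) of a feature's
improvements across the session's programs — the small program counts per
session make the unbiased convention the natural choice. Weights normalize
responsiveness to sum to one; the shrinkage form
*w\_j*(λ) = (1 − λ)*w⁰\_j* + λ/|R| interpolates toward uniform weights
over the responsive set R = {j : r\_j > 0}. λ = 0.1 is the default for the
main analysis, with λ = 0 recovering pure responsiveness weighting; the
stability scan over λ ∈ [0, 0.45] (step 0.05) is always reported because
DWIS is affine in λ, so any rank flip shows up at a grid crossing. If every
feature is unresponsive the weights fall back to uniform with a warning.

Per program, weights are renormalized over that program's unmasked
features — otherwise a single masked cell would silently deflate its
score. DWIS ties break toward the chronologically earlier program and are
reported explicitly.

## Group-level inference

* **Wilcoxon** — one-sided (median improvement > 0), zeros discarded.
  Without ties the exact signed-rank null is used up to n = 25
  (`psignrank`); tied samples are enumerated exactly over midranks up to
  n = 15; beyond that, a normal approximation with tie and continuity
  corrections.
* **FDR** — Benjamini–Hochberg step-up across the feature battery,
  significance at q < 0.05. Significance *counts* are sensitive to
  orientation and normalization conventions; the package always reports
  the count it computed, alongside the per-feature q-values, rather than a
  headline number.
* **Bootstrap** — percentile CIs for medians, 10,000 resamples by default,
  seed mandatory (default 0).
* **Concordance** — REML linear mixed models via `lme4`: improvement model
  `updrs_improvement ~ delta_dwis + (1 | patient_hand)` and the raw-score
  robustness model `score ~ delta_dwis + baseline + (1 | patient_hand)`.
  Wald z inference; singular fits (zero cluster variance) are flagged, not
  fatal. A complementary per-feature model on raw values
  (`value ~ condition + (1 | subject)`) guards the percent-change analysis
  against normalization artifacts.

## Sparse kinematic domains

The domain analysis fits the ℓ1-penalized dictionary-learning form of
sparse PCA (minimize ½‖X − UVᵀ‖² + α‖V‖₁ with unit-ball score columns) to
the patients × features matrix of optimal-program improvements,
column-standardized by default because oriented percent changes live on
wildly different scales (the flag is exposed, so the unstandardized
variant runs too). Hyperparameters are fixed a priori: 3 components,
penalty α = 1. The solver alternates coordinate-descent soft-thresholding
for the loadings with norm-constrained least squares for the scores, is
initialized from the SVD (hence deterministic and, at α = 0, exactly the
top-k principal subspace), fixes each component's sign so its
largest-magnitude loading is positive, and orders components by explained
variance. Because sparse components are correlated, explained variance is
computed on sequentially orthogonalized projections (QR of XV); naive
per-component variances would double-count.

Cross-cohort similarity uses Tucker's congruence Φ on a shared feature
set. The reported 3 × 3 matrix keeps Φ's sign (an inverse structural
relationship is information, not noise); the global statistic is the mean
|Φ| over the index-matched diagonal (component 1 vs 1, 2 vs 2, 3 vs 3
after each cohort's own variance ordering). An optimal-assignment pairing
(maximizing Σ|Φ| over the 3! permutations) is also computed and is what
bootstrap replicates are aligned with before percentile loading CIs are
formed. The global permutation test relabels one cohort's features at
random — refitting the decomposition when improvement data are supplied,
or equivalently permuting loading rows when only loadings are available
(the solver is permutation-equivariant, so the two modes agree) — with
p = (1 + #{null ≥ observed}) / (1 + iters). This null construction is a
design decision of this package: it tests whether the observed
cross-cohort alignment exceeds what arbitrary feature relabeling achieves.

## Synthetic cohorts and what they show

The generators produce: quasi-periodic raised-cosine aperture traces with
per-cycle amplitude/rate drift (the sequence effect), multiplicative
period jitter and additive noise; programming sessions (baseline + 10
programs by default, 15 patients to a cohort) in which one designated
program dominates every generative parameter; improvement matrices with
planted sparse low-rank domain structure; and clustered concordance
records generated on a latent continuous scale then rounded and clipped to
the 0–4 clinical item range (the rounding is the realistic choice — the
planted slope remains recoverable with < 5% bias at the 15 × 10 design).
All generators are pure functions of spec + seed.

Validation sizes are chosen to mirror the study geometry while keeping the
suite fast: 100 seeded sessions for ranking recovery, 150-patient domain
cohorts at 10% noise, 100 replicates × 1000 permutations for null
calibration, 200 replicates for mixed-model CI coverage.

What passing these tests does **not** show: the generator's raised cosine
is not a biomechanical hand model; real traces carry pose-estimation
dropouts, drift, asymmetric open/close dynamics and tremor residue that
the generator deliberately omits. Synthetic recovery therefore validates
the *machinery* (segmentation, scoring, inference, decomposition), not the
clinical sensitivity of any particular feature.

## Known limitations

* The feature battery is a faithful five-family stand-in; the scorer is
  feature-agnostic by design, so alternative catalogs drop in as data.
* Ranking maximizes motor benefit only; side-effect trade-offs
  (dysarthria, paresthesia) are outside the score.
* The permutation null and the sPCA standardization flag are documented
  package decisions; both variants are exposed where the choice matters.
* Cross-therapy congruence speaks to loading *structure* only, never to
  effect-size magnitudes between cohorts.
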