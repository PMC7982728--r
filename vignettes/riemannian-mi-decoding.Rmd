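---
title: "Riemannian tangent-space decoding with discriminative multi-scale filter banks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian tangent-space decoding with discriminative multi-scale filter banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(riembci)
```

## The model

A motor-imagery trial is a multichannel EEG segment
`X ∈ R^{N_c × N_s}`. Because imagined movement expresses itself as
class-dependent modulation of narrow-band oscillatory power with a stable
spatial signature, the second-order statistics of the band-passed signal —
the sample covariance matrix `P = X Xᵀ/(N_s − 1)` — carry essentially all
of the class information. Covariance matrices live in the cone of symmetric
positive-definite (SPD) matrices, which is a curved Riemannian manifold
under the affine-invariant metric. `riembci` uses three standard objects on
that manifold:

* the geodesic distance
  `δ_R(P_1, P_2) = ‖logm(P_1^{-1} P_2)‖_F = sqrt(Σ_i log² λ_i)`,
  where `λ_i` are the generalized eigenvalues of the pair. It is invariant
  under any invertible linear mixing of the channels — re-referencing,
  scaling, and linear volume conduction all leave it unchanged;
* the Karcher (Fréchet) mean, the SPD matrix minimizing
  `Σ_i δ_R²(M, P_i)`; and
* the tangent-space map at a reference `P_𝔊`:
  `s_i = upper(P_𝔊^{-1/2} Log_{P_𝔊}(P_i) P_𝔊^{-1/2})`, the
  whitened matrix logarithm vectorized over its upper triangle. Off-diagonal
  entries are weighted by √2, a convention chosen so that
  `‖s_i‖₂ = δ_R(P_𝔊, P_i)` exactly; this identity is enforced by tests
  at 1e-10. Tangent vectors are ordinary Euclidean vectors, so linear
  classifiers apply.

A note on containers: raw signals stay as dense numeric arrays
(trials × channels × samples) and covariances as matrices, because that is
what signal processing consumes; everything the user reads — band-score
tables, cross-validation results, per-class metrics, feature column
indices — is a tibble, with `tidy()`, `glance()` and `autoplot()` methods
on fitted and evaluated objects.

The assumptions are those of all covariance-based decoders: the signal is
zero-mean (guaranteed here because features are computed on band-passed
data), approximately stationary within the analysis window, and the trial
covariance is well-conditioned enough for the matrix logarithm to be
meaningful.

## Subject-specific band selection

Which frequency bands separate the classes differs across subjects, so the
pipeline screens a grid of 2 Hz sub-bands spanning 2–40 Hz (19 bands). For
each sub-band it computes all pairwise geodesic distances between trial
covariances and forms a distance-based one-way MANOVA pseudo-F:

```
SS_T = (1/N) Σ_{i<j} d_ij²          (total)
SS_W = (1/n) Σ_{i<j, same class} d_ij²   (within)
SS_A = SS_T − SS_W                  (between)
F = (SS_A/(a−1)) / (SS_W/(N−a))
```

for `a` classes with `n` trials each, `N = a·n`. With Euclidean distances on
univariate data this is algebraically identical to Fisher's one-way ANOVA F,
which the test suite verifies to 1e-9 relative error against `lm`/`anova`
(and against an independent distance-based MANOVA implementation). The
statistic requires a balanced design — the `1/n` in `SS_W` is only correct
when every class has the same count — so unbalanced inputs are rejected with
an explicit error rather than silently generalized.

Sub-bands are ranked by descending F (ties break toward the lower frequency,
for determinism); the top G are kept, adjacent survivors are merged, and
each merged band is expanded into every 2, 4, and 8 Hz window (hops 2, 2,
4 Hz) that fits inside it. The width/hop scheme is configurable; the default
reproduces a 43-window parent bank over 4–40 Hz and hence a
`43 × 253 = 10879`-dimensional tangent feature vector for 22 channels and
one time window. Note the screening grid intentionally starts at 2 Hz while
the default multi-scale parent starts at 4 Hz; both are independent
configuration entries.

G defaults to a data-driven choice from {11, 12, 13, 14} by stratified
cross-validation on the training set, jointly with the SVM cost
C ∈ {1e-3, …, 1e2}. Inside `mi_fit()` the per-cell covariances, references,
and tangent blocks are cached across G candidates (the candidates' filter
banks overlap heavily), and the SVM cross-validation runs in an exact SVD
compression of the feature matrix: with a linear kernel, projecting
features onto the right singular vectors of the training matrix changes no
inner product, so the hyperparameter search is exact but runs in at most
`n_trials` dimensions.

`cross_validate_10fold()` is stricter than the internal search: it repeats
*all* data-driven selection — band scoring, G, C, references,
standardization — inside each training fold, so its accuracy estimate never
sees held-out trials. The no-leakage property is tested by corrupting
test-set labels and hashing the fitted weights.

## The classifier

Tangent features are z-scored per column (training statistics only) and fed
to a one-vs-rest linear SVM (`e1071::svm`, one binary machine per class,
argmax of decision values). The choices the literature leaves open are made
explicit here: per-feature standardization (tangent coordinates have
heterogeneous scales and linear SVMs are scale-sensitive), one-vs-rest
reduction (deterministic, simple), and a fixed cost grid. All are
configurable through `mi_config()`.

## The synthetic generator

`simulate_mi_epochs()` emulates the structure of a 4-class, 22-channel,
250 Hz motor-imagery recording: each trial is a spatial mixture of 1/f
background sources (spectral exponent 1.0), plus — for the trial's class —
band-limited Gaussian sources projected through class-specific unit-norm
spatial patterns, plus white sensor noise. Class information therefore
lives purely in the spatial covariance of narrow bands, exactly the
statistic the decoder consumes, and in no other property of the signal.
The default plants the four class rhythms in 8–12, 12–16, 20–24 and
26–30 Hz with gain 2.0 against a unit-amplitude background and sensor noise
of 0.25 — a deliberately clearly-separable regime intended as a functional
benchmark of the pipeline, not as a calibrated model of any particular
dataset. `default_benchmark()` draws two sessions sharing spatial structure
(patterns and mixing derive from the master seed) but with independent
noise realizations, a stand-in for session-to-session transfer.

What the generator does *not* emulate: volume-conduction forward models,
eye/muscle artifacts, within-session nonstationarity, inter-subject
variability of spectral shape. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the machinery (band
recovery, chance-level behaviour under the null, monotonicity in effect
size), not expected accuracy on recorded EEG.

## Numerical choices

* **Karcher mean.** Fixed-point gradient iteration
  `M ← Exp_M(τ · mean_i Log_M(P_i))`, initialized at the arithmetic mean.
  The classical unit step contracts near the solution but its rate
  degrades badly for dispersed, ill-conditioned covariance sets (2 Hz-wide
  bands with a strong planted source produce exactly these), so τ adapts
  multiplicatively — grown 1.3× after an accepted step, halved after a
  rejected one, with no upper cap — and a step is accepted iff it strictly
  lowers the Fréchet cost or lowers the gradient norm. The cost and the
  gradient come from the same whitened matrix logarithms, so the safeguard
  is free. Convergence is declared at gradient Frobenius norm ≤ `tol`
  (default 1e-8, 200 iterations); non-convergence is a hard error carrying
  the last gradient norm. Pipeline cells use `tol = 1e-7`: the matrix-log
  gradient of 22-channel narrow-band covariances has an eigensolver
  precision floor near 1e-8, and 1e-7 on a log-scale quantity is orders of
  magnitude below statistical noise.
* **Eigendecompositions, not inverses.** Distances use a Cholesky-whitened
  symmetric eigenproblem; maps and means use `eig_sym` of symmetrized
  products. No explicit matrix inverse is formed anywhere.
* **Covariance conditioning.** `estimate_scm()` applies the covariance
  formula literally (no mean subtraction — inputs are band-passed, hence
  zero-mean; a `center` flag exists). Shrinkage defaults to 0; a window
  with fewer samples than channels at zero shrinkage is a hard
  rank-deficiency error naming the offending cell, and a nearly singular
  estimate (smallest eigenvalue ≤ 1e-12 × largest) triggers an automatic
  1e-6 relative shrinkage with a warning.
* **Filtering.** 4th-order Butterworth band-pass (the de-facto standard in
  motor-imagery filter banks), applied forward-backward for zero phase so
  covariance structure stays aligned across bands; filters are designed by
  `signal::butter` and applied by a compiled routine with odd-reflection
  padding and steady-state initial conditions. If a requested band is too
  narrow for a stable design at the given rate, the order is reduced until
  the poles are inside the unit circle (with a message). Filters run on the
  full epoch *before* time slicing, so short windows never see filter
  transients.
* **Windows.** Time windows are half-open `[t_start, t_end)` with 0-based
  sample indexing — overlapping windows share bit-identical samples and no
  boundary sample is duplicated. The default catalogue offers
  `[0.5, 3.5)`, `[0.5, 2.5)`, `[1.5, 3.5)` s post-cue (one window by
  default), spanning the execution period of a ~3 s imagery trial at
  multiple scales.
* **Determinism.** Fold assignment uses a seeded RNG recorded in the model;
  two fits with the same data and seed produce identical hyperparameters
  and weights. Ranking ties, window enumeration order, and feature column
  order are all fixed conventions, and every feature column maps to exactly
  one (time window, band, triangle position) triple.

## Problem sizes in the test suite

The unit tests exercise the geometry on random SPD sets of dimension 2–8,
and the pipeline on reduced synthetic configurations (4–8 channels, 6–15
trials per class, 2 s trials) chosen so the full suite runs in minutes;
the structural dimension checks (19 sub-bands, 43 parent windows, 10879
features) and the end-to-end transfer checks run at the full default
geometry (22 channels, 40 trials/class, 4 s at 250 Hz). Chance-level
calibration of nested cross-validation uses 15 trials/class at 6 channels:
small enough for full re-selection in every fold, large enough for the
binomial band around 25 % to be meaningful.

## Limitations

* The pseudo-F screening requires balanced class counts by construction.
* Resampling is out of scope: a model refuses epochs whose sampling rate
  differs from its training data.
* No GDF/EDF reader is bundled; recordings must be converted to the array
  container (RDS or JSON) externally.
* Other SPD metrics (log-Euclidean, Stein), manifold kernels, geodesic
  filtering, and adaptive/online operation are out of scope.
* Accuracy figures obtained on the synthetic benchmark characterize the
  implementation, not expected performance on recorded EEG.
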