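---
title: "Spatially regularized Riemannian classification of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially regularized Riemannian classification of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmdrm)
```

## The problem

A motor-imagery brain-computer interface (BCI) asks a user to imagine a limb
movement and decodes the imagined class from multichannel EEG. The
discriminative signal is second-order: imagining movement changes the power
of sensorimotor rhythms (event-related desynchronization/synchronization) in
the 7--30 Hz band, so a trial is well summarized by the spatial covariance of
its bandpassed samples. Two obstacles make this hard in practice:

1. **Calibration cost.** Covariances are estimated per subject from labeled
   calibration trials. With `N` electrodes the covariance has
   `N(N + 1)/2` free parameters; at 60--118 channels and a few dozen trials
   the estimates are very noisy and classifiers built on them degrade.
2. **Geometry.** Covariance matrices are symmetric positive-definite (SPD)
   and live on a curved manifold. Euclidean operations (arithmetic averaging,
   linear classifiers on raw entries) ignore this and lose accuracy.

This package combines three ideas to address both: spatial filters shrink the
covariance dimension before any manifold computation; the filters themselves
are regularized toward spatial smoothness using the physical electrode
layout; and classification is done with the affine-invariant Riemannian
geometry of the SPD manifold.

## The model

### Riemannian geometry of SPD matrices

For SPD matrices the package uses the affine-invariant metric throughout.
All matrix functions go through the symmetric eigendecomposition
`C = U diag(lambda) U'`, so `C^p`, `logm(C)` and `expm(S)` act on
eigenvalues. The geodesic distance is

    Rd(C1, C2) = || logm(C1^{-1/2} C2 C1^{-1/2}) ||_F = sqrt(sum_i log^2 lambda_i),

which is invariant under any common congruence `C -> A' C A` with invertible
`A` — the property that makes the downstream classifier indifferent to linear
mixing of the sensors. The Fréchet (geometric) mean of a set minimizes the
sum of squared geodesic distances and is computed by the standard fixed-point
iteration: project to the tangent space at the current estimate with the
logarithmic map, average there, map back with the exponential map.

Numerical choices: inputs are symmetrized as `(C + C')/2` before any
decomposition (floating-point asymmetry otherwise yields complex eigenpairs);
eigenvalues below `1e-12` times the largest are clipped with a warning before
logs and negative powers, because real covariance estimates can be
numerically rank-deficient; the mean iteration starts at the arithmetic mean
and stops when the Frobenius norm of the tangent-space mean falls below
`1e-8` (default) or after 50 iterations, in which case it warns and returns
the last iterate. Only batch recomputation of the mean is provided; no
online update rule is implemented.

### Covariance estimation

A trial `X` (channels x samples) is summarized as `C = X X' / tr(X X')`.
No mean subtraction is applied: bandpassed EEG is approximately zero-mean,
and the raw outer product keeps the estimator exactly proportional to the
per-channel signal energies the spatial filters operate on. Trace
normalization removes per-trial global amplitude, so the estimate is
invariant to trial rescaling.

Class covariances can be accumulated as the literal **sum** of trial
covariances or as their **mean**. The mean is the default: when the penalty
`alpha K` is added to a class covariance, a sum would make the effective
`alpha` depend on the number of training trials, whereas the mean keeps one
`alpha` grid meaningful across calibration sizes. The summed form is
retained via `covariance_mode = "sum"` for literal reproduction.

### CSP and its spatially regularized variant

Common spatial patterns (CSP) finds filters `w` extremizing the Rayleigh
quotient `w'C1w / w'C2w`, i.e. the generalized eigenproblem `C1 w = lambda
C2 w`; the `k` leading and `k` trailing eigenvectors extremize the variance
ratio between the classes.

The spatial prior enters through a graph Laplacian built from electrode
positions: `G_ij = exp(-||v_i - v_j||^2 / (2 r^2))` is a Gaussian adjacency
over the montage, `K = D - G` with `D = diag(rowSums(G))`, and
`w'Kw = (1/2) sum_ij G_ij (w_i - w_j)^2` measures the spatial roughness of a
filter. (The self-adjacency terms `G_ii = 1` enter `D` exactly as defined
and cancel in the quadratic form.) The regularized objectives penalize the
denominator,

    J1(w) = w'C1w / (w'C2w + alpha w'Kw),   J2(w) = w'C2w / (w'C1w + alpha w'Kw),

leading to the matrices `M1 = (C2 + alpha K)^{-1} C1` and
`M2 = (C1 + alpha K)^{-1} C2`. The filter bank stacks the `k` leading
eigenvectors of `M1` then the `k` leading eigenvectors of `M2`, each block
in decreasing eigenvalue order. At `alpha = 0` this span coincides with
plain CSP. The non-symmetric eigenproblems are solved through their
whitened symmetric equivalents (`B^{-1/2} C B^{-1/2}` with
`B = C + alpha K`), which guarantees real eigenpairs; filters are scaled to
unit norm with the first nonnegligible coefficient positive, making the bank
deterministic under ties.

`r` is in the units of the electrode coordinates. The synthetic montages
here use a unit head radius, where nearest-neighbor spacing is roughly
0.2--0.5 depending on channel count; `r` of that order makes the penalty
active, while much smaller `r` effectively turns it off (`G` approaches the
identity and `K` vanishes).

The default `k = 3` (six virtual channels) is standard CSP practice,
balancing discriminative capacity against the dimension of the projected
covariances downstream.

### FGDA geodesic filtering

Projected trial covariances still carry tangent-space noise. Fisher geodesic
discriminant analysis (FGDA) fits Fisher discriminant directions to the
covariances vectorized in the tangent space at their Riemannian mean
(upper-triangular vectorization with off-diagonal entries weighted by
`sqrt(2)` so Euclidean and Frobenius norms agree), then filters any
covariance by projecting its tangent vector onto the span of the top
discriminant directions and mapping back to the manifold. The filter
preserves dimension and SPD-ness and is idempotent.

Two regularization decisions are deliberate:

* `n_components = 1` by default — a binary Fisher problem has a single
  nontrivial discriminant.
* The within-class scatter is shrunk toward a scaled identity
  (`shrinkage = 0.05` by default) because the tangent dimension
  `2k(2k + 1)/2 = 21` at `k = 3` can exceed the number of calibration
  trials, making the raw scatter singular.

The filter is fit only on training covariances and applied unchanged to test
covariances.

### MDRM classification and evaluation

The classifier stores one Riemannian mean per class and assigns a test
covariance to the geodesically nearest mean. Exact ties go to the lowest
class index with a warning. Per-class distances are returned alongside the
labels to support rejection heuristics downstream.

Binary evaluation reports accuracy `(a + b)/(a + b + c + d)` from the
confusion counts and the chance-corrected kappa
`(accuracy - random)/(1 - random)`, where the accuracy of a random system
with the same marginals is `((b + c)(b + d) + (d + a)(c + a))/(a+b+c+d)^2`.
When that chance accuracy is exactly 1 (single-outcome degenerate case)
kappa is reported as `NA`.

## The pipeline

`fit_srmdrm()` chains: class covariances -> SRCSP filters -> projection of
every trial to `2k` virtual channels -> unit-trace covariances of the
projected trials -> FGDA fit and geodesic filtering -> per-class Riemannian
means. `predict_srmdrm()` applies the fitted projection, filtering and
nearest-mean rule to test trials. Internally the projected covariance is
computed directly as the trace-normalized `W C W'` of the full-dimension
trial covariance — algebraically identical to projecting the time series
first (`(WX)(WX)' = W (XX') W'` and trace normalization removes the
constant), and much cheaper inside cross-validation; a test asserts the
equivalence against the literal signal-space path.

Preprocessing applies a 5th-order Butterworth 7--30 Hz bandpass
forward-backward (zero phase; the net response is the squared magnitude of
the single-pass design), then cuts the half-open epoch `[0.5, 2.5)` s after
the cue — exactly 200 samples at 100 Hz, 500 at 250 Hz. Zero-phase filtering
is standard motor-imagery practice because phase distortion would shift
signal energy across the epoch boundary; a single-pass causal mode is
available by flag.

### Hyperparameter selection

The grids default to `alpha in 10^-10 ... 10^-1` and `r in 0.01 ... 0.1`
(100 settings). `grid_search()` evaluates each setting by stratified
cross-validation on the training set only — 5 folds, switching to
leave-one-out when the smallest class has fewer than 10 trials (e.g. a
28-trial calibration). Ties in mean CV accuracy break toward larger `alpha`,
then larger `r`: among equally accurate settings, prefer the smoothest
filters. How the original hyperparameter values per subject were selected is
not specified in the source material; training-set cross-validation is this
package's choice, made to keep test data strictly out of all fitting (the
fitting functions only ever receive the training set, so leakage is
excluded by construction).

### Baselines

`run_baselines()` runs, under identical preprocessing: plain CSP with a
Fisher linear discriminant on log-variance features of the projected trials
(the conventional CSP decoding chain; the classifier choice is ours), and
plain MDRM on full-dimension trial covariances. At 118 channels with 28
trials the full-dimension mean iteration may warn about non-convergence —
that is the small-sample breakdown the spatially regularized reduction is
designed to avoid, and the warning deliberately surfaces it.

## The synthetic generator

`simulate_trials()` emulates exactly the statistical structure the method
assumes, with known ground truth:

* **Sources** are band-limited (7--30 Hz) Gaussian noise, zero-phase
  filtered with generous padding so transients never reach the trial, and
  standardized to unit variance. A parametric AR model would add spectral
  realism, but the classifier consumes only second-order statistics, so
  band-limited Gaussian processes are sufficient and simplest.
* **Class structure**: the first `n_discriminative` sources have their
  variance multiplied by `class_variance_ratio` in class 1 — the ERD/ERS
  analogue. At ratio 1 the classes are distributionally identical (the null
  control); the class-covariance difference lies in the span of the
  discriminative mixing columns by construction.
* **Mixing columns** are samples of a squared-exponential Gaussian process
  over the montage with correlation length `pattern_smoothness`; this
  mirrors the penalty's smoothness prior, so instances exist where the
  regularization demonstrably helps, with planted truth to verify against.
* **Sensor noise** is spatially correlated (a short-range smooth field plus
  a white floor), at `noise_power` relative to unit source power.
  Optionally, a few isolated channels receive strong independent noise —
  the scenario in which penalizing rough filters is most clearly justified.
* **Montages** are deterministic Fibonacci lattices on the upper unit
  hemisphere: quasi-uniform for any channel count.

What the generator does **not** emulate: nonstationarity across trials,
ocular/muscular artifacts, volume-conduction forward physics, inter-subject
variability, and non-Gaussian source statistics. Passing the synthetic
recovery suite therefore shows the implementation is correct and behaves as
the theory predicts under its own assumptions — it does not certify accuracy
figures on real recordings.

`dataset_preset()` mirrors the shapes of the three public benchmarks this
family of methods is usually evaluated on (118 channels at 100 Hz with
per-subject splits down to 28 training trials; 60 and 22 channels at
250 Hz), so scale behavior can be exercised without any data download.

## Study sizes used in the verification suite

The shipped tests and the acceptance script compute everything they assert.
Geometry properties run on 200 random congruence triples (dimensions 2--16)
and 100 random montages. End-to-end checks use: an easy instance (16
channels, power ratio 8, low noise, 40 training / 60 test trials) expecting
near-perfect recovery; a null instance (ratio 1, 200 balanced test trials)
expecting chance accuracy; and the small-calibration comparison — 60
channels, 20 training trials, ratio 2, sensor noise 1.5, smooth patterns,
hyperparameters at the montage scale (`alpha = 0.01`, `r = 0.4`), 20
seeded replicates — where the spatially regularized pipeline is expected to
match or beat full-dimension MDRM on mean accuracy. The conditions of that
comparison were chosen so both classifiers sit well below ceiling;
at-ceiling instances cannot distinguish the methods. The benchmark-scale
smoke test runs the full 100-setting grid search at 118 channels with a
28-trial calibration.

## Known limitations

* Binary classification only; the evaluation formulas are binary as stated.
* The affine-invariant metric only; log-Euclidean or Stein metrics are not
  provided.
* No online/adaptive recalibration; means are recomputed in batch.
* Very ill-conditioned covariance sets (e.g. 118-dimensional SCMs from
  200-sample trials) can exhaust the mean iteration's 50 iterations; the
  result is returned with a warning and remains usable, but slow convergence
  there is a real property of the geometry, not an implementation artifact.
* The kernel width `r` is montage-scale dependent; grids should be chosen
  relative to the coordinate units of the montage in use.
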