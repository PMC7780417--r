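---
title: "Spanned-subspace regression for ERP analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanned-subspace regression for ERP analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roldsis)
```

## The model

We relate a scalar stimulus attribute $y$ to a high-dimensional neural
response $\mathbf{x} \in \mathbb{R}^N$ through the affine functional
$y = a + \mathbf{b}^\top \mathbf{x}$. In an ERP study the available
observations are a handful of trial-averaged responses
$\mathbf{x}_1,\dots,\mathbf{x}_M$ with $M \ll N$ (here $M = 5$ stimuli,
$N = 128$ wavelet features), so least squares is underdetermined:
any $\mathbf{b}$ that interpolates the data plus any vector orthogonal
to all centered observations is also a solution.

The package's core assumption is that the *neurophysiological axis*
$\mathbf{b}$ lies in the $(M-1)$-dimensional subspace spanned by the
centered observations. Writing $\mathbf{m}$ for the observation mean
and $V$ for an orthonormal basis of the centered span, each observation
has subspace coordinates $\mathbf{z}_i = V^\top(\mathbf{x}_i -
\mathbf{m})$ and the model becomes $y_i = c + \mathbf{d}^\top
\mathbf{z}_i$ — $M$ equations, $M$ unknowns. With linearly independent
observations this system has a unique exact solution, from which
$\mathbf{b} = V\mathbf{d}$ and $a = c - \mathbf{d}^\top V^\top
\mathbf{m}$. Two consequences shape everything downstream:

* **Exact interpolation.** The in-sample residual is identically zero;
  the method has *no* free parameter and needs no cross-validation.
* **Minimum-norm equivalence.** The fitted axis equals the
  minimum-norm exact solution of the underdetermined problem
  (pseudoinverse of the centered matrix applied to the centered
  attributes) — the spanned-subspace constraint and the minimum-norm
  principle select the same vector. The test suite checks this
  equivalence against `MASS::ginv` on random instances.

The method is the limiting case of principal component regression with
all $M-1$ components retained. It is built for *inference* — reading
the axis as a time-frequency pattern — rather than prediction: with
$M = 5$ observations there is no held-out data to predict.

When is the span assumption reasonable? When the averaged observations
are reliable (high SNR after averaging), the true functional, whatever
it is, must act on the part of feature space the data actually occupy;
restricting to the span discards only directions about which the data
carry no information.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sampling rate `fs` | 5000 | Hz | auditory-ERP acquisition rate of the emulated experiment |
| epoch length `S` | 2048 | samples | ~0.41 s, dyadic for the level-8 DWT |
| baseline `pre_stimulus_s` | 0.15 | s | standard pre-stimulus window |
| DWT `level` | 8 | — | approximation block reaches 0–9.77 Hz (θ band) |
| `retain_hz` | 156.25 | Hz | keeps θ, α, β, γ bands: V8..W5, 128 coefficients |
| rank tolerance `rtol` | 1e-10 | relative | double-precision margin for $M \le 10$ |
| bootstrap `B` | 100 | replicates | reference reliability analysis size |
| psychometric `separation_cap` | 10 | 1/ms | beyond this the logistic fit has effectively diverged |
| rejection threshold | 5 × median peak | µV | automated surrogate for visual artifact inspection |

## Feature extraction

Trials are baseline-corrected (pre-stimulus mean subtracted per trial),
optionally screened by an amplitude threshold, averaged, and
transformed with the level-8 orthogonal DWT using the length-8
least-asymmetric (symlet) filter. Naming differs across libraries: this
filter is "la8" in the classic R wavelet packages and "sym4" (4
vanishing moments) elsewhere; the coefficients are identical and are
hard-coded at full double precision, with their orthonormality
identities ($\sum h = \sqrt2$, unit energy, even-shift orthogonality)
asserted in the tests.

Boundary handling is periodic (circular), which keeps the transform
exactly orthogonal — Parseval holds to machine precision and the
inverse is the transpose. Retained coefficients are ordered
approximation first, then detail blocks in increasing frequency; for
2048 samples at 5 kHz this is V8 (0–9.77 Hz, 8), W8 (9.77–19.5 Hz, 8),
W7 (19.5–39.1 Hz, 16), W6 (39.1–78.1 Hz, 32), W5 (78.1–156 Hz, 64) —
128 features. Band edges are dyadic, $f_s/2^{\ell+1}$; they are stored
exactly (9.765625 Hz, not 9.77) and rounded only for display.

Two numerical caveats the tests respect:

* A *time-domain* sinusoid "inside" a band still leaks a little energy
  through the filter's transition bands. A circularly periodic 2.44 Hz
  tone round-trips through decompose/reconstruct at RMS < 1e-6, but a
  non-periodic 5 Hz tone leaks ~1e-2 RMS at the circular boundary.
  What *is* exact is idempotence: reconstruction from retained
  coefficients is a projection, so a second round trip reproduces the
  first to < 1e-8.
* `estimate_snr` (ERP variance over mean within-trial residual
  variance) is one of several defensible estimators and is biased
  upward for small trial counts; it is a diagnostic, not a calibrated
  measurement.

## Psychometrics

The identification curve is the two-parameter sigmoid
$p(t) = 100/[1 + e^{\beta(t - t_0)}]$ (in percent; $t$ = VOT in ms).
Fitting is plain maximum-likelihood logistic regression via `glm`: the
robust-weighting variant used in some analysis pipelines protects
against outlier responses that the simulated data do not contain, and
would test a third-party implementation rather than this model. As
printed, the sigmoid *decreases* in $t$ for $\beta > 0$, while the
physiological orientation (/ta/ probability rising with VOT) makes the
fitted $\beta$ negative; the package stores $\beta$ as fitted and
defines the maximal slope as $(100/4)|\beta|$ %/ms, so all derived
quantities are orientation-invariant. Perfect separation (step-like
data) is flagged when $|\beta| > 10$/ms rather than chased to
divergence. The 0% and 100% points of the curve are asymptotes; stimulus
selection returns the continuum endpoints (−52, +16 ms) for them, and
the closed-form inverse $t = t_0 + \ln(100/p - 1)/\beta$ otherwise.

## Axis geometry and reliability

The angle between two fitted axes uses the absolute dot product —
axes are directions, not oriented vectors — and therefore lies in
[0°, 90°]. For the bootstrap reliability analysis, each replicate
resamples every stimulus's trials with replacement (one resample per
replicate, both attributes fitted on it), refits, and stores unit axes
*sign-aligned to the full-data axis*: antipodal points on the
hypersphere represent the same axis, and unaligned signs would split
each cluster in two and corrupt the PCA. The 2B axes are mapped to
$N-1$ hyperspherical angles (recursive convention, polar angles in
$[0, \pi]$, final azimuth in $(-\pi, \pi]$; any fixed convention works
since PCA/LDA operate within one), PCA is applied centered and
unscaled (the angles share units), the first two PC scores are
classified by Fisher LDA with shared covariance, and the
misclassification count against the true labels measures axis
distinguishability: 0 for well-separated axes, about B at chance.
Degenerate clouds (identical replicates, or the two groups coinciding
pointwise) are reported as errors rather than classified.

## Cross-validated benchmarking

The comparison machinery holds every method to the same data: trials
are stratified into k folds per stimulus; training observations are
the per-stimulus averages within each training fold ($M(k-1)$
observations, attributes repeated), test observations the held-out
fold's averages. This aggregation is a design choice — it keeps the
spanned-subspace system even-determined while giving all methods
identical training sets. One edge case follows from it: with noiseless
trials all fold averages coincide and the stacked training matrix is
rank-deficient; the benchmark adapter then falls back to the
minimum-norm exact solve (identical to the spanned-subspace solution
on the distinct observations), while the core fit still raises its
rank error, as it should on collinear input.

Penalties are tuned by bracketed derivative-free minimization
(`optimize` on $\log_{10}\lambda$, endpoints also checked) rather than
literal gradient descent: the CV error is noisy and non-smooth in the
penalty, and the named procedure is a goal, not an algorithm. Sparse
PLS is tuned by exhaustive search over the component count crossed
with the same 1-D search over the sparsity parameter. Ridge uses the
exact M×M dual form (equal to the primal to 1e-8 in tests); lasso
delegates to glmnet; sparse PLS is a native NIPALS implementation with
soft-thresholded covariance directions, since no established SPLS
implementation is available in the supported dependency set.

## The synthetic world

The generator plants two unit axes at an exact angle θ, builds M
templates that satisfy *both* affine attribute relations exactly
(coordinates in an orthonormal frame containing the axes: two
coordinates pinned by the constraints, the rest random), and adds
i.i.d. Gaussian feature noise calibrated so the per-trial SNR matches
a target in dB. Defaults mirror the emulated experiment: 5 stimuli ×
200 trials, 128 features, ψ = (0, .05, .5, .95, 1), φ endpoints −52
and +16 ms with interior values derived from the configured
psychometric curve (β = −0.2/ms, t₀ = −22 ms), per-trial SNR −12 dB.
Noise lives in feature space: the DWT is orthogonal, so white noise
maps to white noise and the SNR bookkeeping is identical in either
domain. Averaging $n$ trials raises the SNR by $10\log_{10} n$ dB, the
classical motivation for ERP averaging (−12 dB + 23 dB ≈ +11 dB at
200 trials).

**What a green test establishes — and what it does not.** The
synthetic world validates the algebra (exact recovery at zero noise),
the calibration (measured SNR within 1 dB of target), and qualitative
behaviour under isotropic Gaussian noise. It does not emulate real
EEG: no N1–P2 morphology, no 1/f or oscillatory noise spectrum, no
inter-trial correlation, no artifacts. One structural feature deserves
emphasis: with *unit* axes, the data's extent along each axis is fixed
by the attribute units — ~68 ms for VOT against ~1 for the identification
proportion — and ψ is close to an affine function of φ, so the
ψ-specific variation in the templates is tiny (the centered template
matrix is near rank-deficient). Under isotropic noise at the −12 dB
raw-trial level, that variation is buried at any realistic trial
count, and the recovered inter-axis angle is noise-dominated; the
"error shrinks with trial count" property is therefore exercised at a
30 dB per-trial SNR, the regime where averaging transitions the
problem into informativeness. Real recordings evidently occupy a more
favourable regime (structured signal, structured noise); the synthetic
result should be read as a statement about the estimator, not about
achievable EEG practice.

θ = 0 is accepted by `make_axes` (both axes equal) but rejected by the
template builder: two *independent* affine constraints cannot
generally be satisfied along a single direction.

## Numerical choices

* PCA of the observations via SVD of the row-centered matrix, never
  the N×N covariance: better conditioned for $N \gg M$.
* Rank tolerance: the fit refuses input whose $(M-1)$-th singular
  value is ≤ 1e-10 × the largest — duplicated or collinear
  observations produce a clear error, not a silent near-singular
  solve.
* Basis sign convention: each basis vector's largest-magnitude entry
  is made positive; the fitted axis is provably invariant to this (and
  tested).
* The M×M system is solved densely (`solve`); at $M \le 10$ nothing
  iterative is warranted.
* Attribute equivariance: $y \mapsto \alpha y + \gamma$ maps the fit
  to $(\alpha\mathbf{b}, \alpha a + \gamma)$ — tested, and the reason
  the φ (ms) and ψ (proportion) fits need no common scaling.
* `M = 1` is rejected (no span); `M = 2` is the minimal case (a line).

## Known limitations

* Single-channel pipeline: no electrode topographies, no spatial
  filtering.
* The two-parameter sigmoid has no lapse/guess rates; extreme
  percentages map to continuum endpoints by convention.
* The benchmark reports CV errors, not significance: formal
  mixed-model comparison of methods is out of scope.
* Bootstrap reliability assumes the per-stimulus trial pools are
  exchangeable; slow drifts across a session would violate this.
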