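---
title: "Models and methods behind coilbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coilbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coilbias)
```

# Scope

`coilbias` studies how receive head coils with different spatial
sensitivity profiles bias standard structural, diffusion and resting-state
MRI analyses, and how voxel-specific scaling factors can remove that bias.
Everything runs on synthetic paired-coil cohorts whose ground truth is
known by construction; all analysis stages equally accept real NIfTI-1
volumes. This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open.

# The forward model

## Anatomy

A subject is a nested-ellipsoid "head": a CSF rim (5 mm), a gray-matter
shell (16 mm) and a white-matter core inside an outer surface with semi-axes
70 x 75 x 65 mm, all jittered per subject (3% SD, truncated at 2.5 SD so
every head fits a 192 mm field of view). Class boundaries are anti-aliased
over one voxel, which creates the partial-volume voxels that drive the
segmentation-bias mechanism; the three partial-volume maps plus background
sum to one at every voxel by construction. GM shell volume exceeds WM core
volume with the default radii, as in real cortex-dominated tissue budgets.
Inter-subject variability is shape-parameter jitter on a shared grid —
there is deliberately no registration stage, so "volume differences" are
differences of smoothed partial-volume maps on the common grid. This is a
semantic difference from Jacobian-modulated VBM and is the main reason the
synthetic results are qualitative, not quantitative, analogues of
full-pipeline results.

## Coils

Coils are parametric multiplicative gain fields, not electromagnetic
simulations; the package characterizes a coil exactly the way an SNR map
does. The 8-channel archetype is
`gain = 1 + 0.4 * anterior_ramp - 0.35 * central_dip` (Gaussian dip, SD
22% of the grid extent); the 32-channel archetype is
`gain = 1 + 0.25 * posterior_boost` (Gaussian, SD 30%). The defaults were
chosen once so that the qualitative signatures hold: the 8CH anterior-third
mean gain exceeds its central-third mean by at least 15%, the 32CH field has
a smaller spatial coefficient of variation than the 8CH field, and its
posterior third dominates its anterior third. Noise is a single complex
Gaussian sigma per coil (default 0.03 against tissue intensities of
0.3/0.6/0.9), applied as the magnitude of `(signal + N, N)` — i.e. Rician
for T1 and DWI. BOLD uses additive Gaussian noise on a mean-free
fluctuation signal, since its analysis operates on high-SNR mean-removed
series. The signal (not the noise) is multiplied by the gain, so a gain
boost raises local SNR — which is what makes the posterior 32CH
connectivity advantage reproducible; a noise-scaled-by-gain convention
would invert that direction and contradict the phenomenon being modeled.

Coil-specific acquisition differences in DWI (slice count, TR, SENSE
factor) are reduced to a configurable per-coil noise-amplitude ratio; the
TR effect is negligible when TR is much longer than five T1 of white
matter. A hemispheric MD asymmetry can only be produced by explicitly
configuring a left/right multiplicative bias field (`dwi$md_bias`); it is
never active by default, because the corresponding real-data observation
has no known mechanism worth baking into a generator.

## Modalities

* **T1**: partial-volume mixture of class means times gain, Rician noise.
  `contrast_shift` scales the GM/WM mean separation about its midpoint for
  one coil — the minimal model of "this coil renders tissue contrast
  differently", which is the mechanism behind coil-dependent segmentation.
* **DWI**: 60 non-collinear single-shell (b = 1000 s/mm²) directions from a
  spherical Fibonacci spiral plus one b = 0; signals
  `S0 * exp(-b gᵀ D g) * gain` from a ground-truth tensor field (prolate
  WM tensors, eigenvalues (1.6, 0.3, 0.3)e-3 mm²/s, along a smooth
  circumferential direction field; isotropic GM 0.8e-3 and CSF 3.0e-3).
* **BOLD**: eight geometric Gaussian-blob network maps at canonical
  locations (named after the standard resting-state networks) times
  band-limited (0.01–0.1 Hz) unit-variance random time courses, plus WM and
  CSF nuisance fluctuations; 200 volumes at TR 2.2 s by default. The blob
  templates are synthetic stand-ins — real template maps on the same grid
  can be supplied anywhere a template set is accepted.

# Analysis chain

## SNR maps

The signal and noise-only single-slice images are tiled into non-overlapping
16 x 16-voxel ROIs (trailing partial blocks discarded — the tiling origin is
otherwise arbitrary and discarding avoids edge bias), and each ROI gets
`SNR = mean(signal) / (sqrt(2/(4-pi)) * SD(noise))`. The factor converts the
SD of a Rayleigh-distributed (signal-free magnitude) sample into the
underlying complex-channel sigma. Sample (n−1) SD is used; on 256-voxel
ROIs the difference from the population SD is negligible but it must be
fixed for reproducibility. Regional summaries (posterior/central/anterior
thirds) are computed over ROIs that fully cover the object (at least 95% of
voxels above 30% of the robust image maximum), since partially covered edge
ROIs otherwise dominate the thirds. Rendered maps use a fixed 0–85 color
scale for cross-coil comparability. Calibration: for true A/sigma ≥ 5 the
median ROI estimate is within 10% of truth; below that the Rician mean bias
(≈ sqrt(A² + sigma²)) becomes visible.

## VBM-lite

Bias correction fits a low-order 3-D polynomial (order =
`clamp(round(extent / (2 * smoothness_mm)), 1, 4)`, default smoothness
50 mm → order 2 on a 192 mm grid) to the log-intensities of the brightest
quartile of in-mask voxels — approximately one tissue class (WM), so the
fit tracks gain rather than anatomy — in two passes, re-selecting the
bright set on the corrected image. The exponentiated field is normalized to
mean 1 over the mask; a second application changes an already-corrected
image by well under 1% RMS.

Segmentation is a plain 1-D three-class Gaussian-mixture EM on
bias-corrected intensities with k-means initialization (fixed seed) and
classes relabeled by ascending mean to CSF < GM < WM. There is no Markov
random field spatial prior: the claim under test is contrast-driven
misclassification, which plain EM exhibits; spatial regularization would
only blur that signal. Convergence is declared when the mean log-likelihood
gain drops below `tol` (1e-6) with a 500-iteration cap; non-convergence is
reported, not hidden. Posteriors serve as partial volumes.

Smoothing uses a separable discrete Gaussian (truncated at 4 sigma,
renormalized; zero boundary, so interior-supported maps conserve mass),
default sigma 3 mm, i.e. FWHM `2 sqrt(2 ln 2) * 3 ≈ 7` mm.

## DTI-lite

Unweighted ordinary least squares on the log-signal with the shared design
matrix; weighted LS or robust variants would change low-SNR behavior but
OLS is the reproducible baseline. Voxels with any non-positive signal are
flagged and excluded. Eigenvalues come from the closed-form (trigonometric)
solution for symmetric 3 x 3 matrices, vectorized over voxels; negative
eigenvalues (noise) are clamped to zero and flagged, keeping FA in [0, 1]
and MD non-negative. The analysis mask is `mean FA ≥ 0.2` where the mean is
taken over all subjects and both coils — the symmetric choice when the
provenance of the mean image is ambiguous. No TBSS skeletonization:
comparisons are voxelwise inside the mask.

## Resting-state chain

High-pass filtering regresses out an intercept plus cosine *and* sine terms
at the discrete-cosine frequency grid `k / (2 N TR)` for all `k` with
frequency below the 0.01 Hz cutoff; the sine terms make attenuation
phase-independent (a cosine-only basis leaves ~12% of an odd-phase drift).
Smoothing is volume-wise Gaussian at 6 mm FWHM (sigma ≈ 2.548 mm).

Dual regression: stage 1 regresses each time point's image on all network
and nuisance maps jointly; stage 2 regresses each voxel's series on the
stage-1 time courses, after normalizing each non-trivial time course to
unit variance (the FSL `dual_regression` convention). Normalization is the
package's resolution of a genuine ambiguity: with raw time courses a
doubled fluctuation amplitude is absorbed into the time course and betas do
not move; with normalization betas are linear in amplitude and both betas
and z are invariant to rescaling any template map. z is beta over its OLS
standard error from the stage-2 residuals (no prewhitening — the synthetic
noise is white by construction; on real data these z values are nominal).
Maps whose stage-1 time course is numerically zero (networks absent from
the data) are dropped from the stage-2 design and get zero beta/z maps; a
rank deficiency among non-trivial time courses is reported as an error
naming the offending maps.

## Paired inference

The paired design is realized as a one-sample sign-flip test on
per-subject difference maps: per voxel `t = mean(d) / (sd(d)/sqrt(n))`,
zero-variance voxels set to t = 0 (with a relative rounding guard so exact
equality is detected). TFCE integrates
`extent(h)^E * h^H * dh` over 100 thresholds spanning (0, max(stat)] with
H = 2, E = 0.5 and 26-connectivity — the method's canonical defaults. The
step size adapts to the map maximum and the top threshold is computed as
`hmax * (k/n_steps)` so the peak voxel always enters at the top step; this
keeps the `c^(H+1)` homogeneity of TFCE exact under positive rescaling.
The implementation adds voxels in descending order into a union-find,
touching each supra-threshold voxel once per step; the permutation loop
(sign flips, t, TFCE, max) runs entirely in C++.

FWE correction uses the permutation distribution of the maximum TFCE value
over the mask, per direction; `p(v)` is the fraction of null maxima at or
above the observed value, with the observed labeling always included, so
p ≥ 1/n_perm. When `2^n ≤ n_perm` the sign-flip group is enumerated
exactly and results are seed-independent. The observed t and TFCE maps are
taken from the identity permutation inside the same C++ loop, so observed
and null values share bit-identical arithmetic — otherwise last-ulp
differences between two correct implementations of the same t-statistic
can flip ≥ comparisons at structural ties. Each one-sided direction is its
own multiplicity-corrected family at alpha (as in FSL randomise); the
union of both directions would control only at ~2 alpha.

Effect summaries pool the significant voxels: each subject contributes its
mean over the mask, the effect size is the paired Cohen's d of those
per-subject differences, and percent change uses the 8CH (baseline) mean
as denominator. Pooled-SD d and other voxel-weighting choices are
configurable in principle; the subject-level d_z is the estimator matched
to the within-subject design.

## Harmonization

`split_cohort` sorts each sex stratum by age and alternates assignments
(the alternation phase carries across strata), then rebalances to the
requested template size by moving the subjects whose age is closest to the
receiving group's mean — deterministic and auditable; the seed only breaks
age ties. `estimate_scaling` divides the template-mean 32CH image by the
template-mean 8CH image, restricted to voxels where the 8CH mean exceeds
5% of its robust (99th-percentile) maximum — division by near-zero air
voxels is otherwise unbounded — and median-filters the ratio with a cubic
window of odd side nearest to 5 mm / voxel size. The 5 mm default targets
millimetre-resolution data; at the 6 mm demo grid it degenerates to a
single voxel (a no-op), so the demo-scale analyses hold the window at
3 voxels (`filter_mm = 18`) — the filter's role is suppression of template
noise in the ratio, and with it inoperative that noise is shared by every
validation subject and acts as a spurious systematic coil effect.
Outside the valid mask the ratio is
1. Scaling is applied to raw intensity images per modality before the
downstream analysis (T1 before segmentation, DWI volumes before the tensor
fit, BOLD before dual regression): scaling raw images is the only choice
under which the downstream nonlinear stages see harmonized inputs, and the
stage at which the original procedure applied it is not decidable from the
available description. A field carries its modality label and refuses to
be applied across modalities. `validate_harmonization` enforces
template/validation disjointness and re-runs the paired inference before
and after scaling.

# Numerical and testing choices

* **Problem sizes.** The test suite and acceptance script run on 32³ grids
  at 6 mm (a 192 mm FOV), cohorts of 12–39 subjects, 250–500 permutations,
  and 60–200 replicate cohorts for frequency calibrations. These are the
  package's demo scale: large enough for the spatial mechanisms (partial
  volume, smoothing, clustering) to operate, small enough for a single CPU.
* **Determinism.** Every stochastic function takes a seed; cohort seeds
  derive from one master seed; the RNG state of the caller is restored.
  Exhaustive permutation results are seed-free by construction.
* **Type-I calibration.** Null cohorts are pairs of i.i.d. smoothed noise
  maps. Over 200 cohorts the per-direction frequency of any
  FWE-significant voxel is required to fall inside the 95% binomial band
  around 0.05 — a two-sided check: both inflation and over-conservatism
  fail.
* **What passing does not show.** The generator has no motion, no
  registration error, no scanner drift, no k-space/SENSE reconstruction
  effects, and its "anatomy" is three smooth shells. Passing tests
  demonstrate the correctness and calibration of the estimators and
  inference machinery, and the qualitative reproduction of the coil-bias
  mechanisms — not quantitative agreement with any particular scanner pair.
  In particular the headline percent-change magnitudes of real cohorts are
  properties of real anatomy and coils and are not targets here.

# Known limitations

A scaling field estimated from a finite template carries frozen estimation
residue that is *common to every validation subject*; the paired sign-flip
test, which is calibrated (verified against the true gain-ratio field),
correctly detects that residue as a small real effect, so post-harmonization
detection frequencies can sit somewhat above the nominal level in one
direction even for a purely multiplicative coil difference. The effect
shrinks with template size and with the median filter's effective reach,
which at coarse demo voxels is far below what the same 5 mm kernel achieves
on millimetre-resolution data. The original procedure's own validation
likewise reported small residual areas.


* Segmentation has no spatial prior, so very low SNR inflates class noise
  relative to MRF-based tools.
* OLS tensor fitting is biased at low SNR (Rician floor); the tests pin the
  bias below 5% at SNR 20 but make no claims below that.
* The registration-free design cannot express between-subject topology
  differences; harmonization validity on real data additionally depends on
  registration quality, which is out of scope.
* Dual-regression z-values assume white residuals; autocorrelated real BOLD
  noise would make them optimistic (the paired permutation inference
  downstream does not rely on their calibration).
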