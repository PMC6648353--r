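# coilbias

Paired head-coil MRI bias: simulation, inference, and voxel-specific
scaling-factor harmonization.

## The problem

Multi-centre and longitudinal neuroimaging studies routinely pool MRI data
acquired with different receive head coils (for example an 8-channel and a
32-channel phased array). Even with harmonized acquisition protocols, the
coils differ in their spatial sensitivity (gain) profiles — an 8-channel
array is typically brightest frontally with a drop in central and medial
areas, while a 32-channel array is more homogeneous with a posterior boost.
These gain differences propagate through standard analysis chains: they
shift gray/white-matter contrast and therefore tissue segmentation in
voxel-based morphometry (VBM), bias diffusion-tensor metrics (FA, MD), and
modulate apparent resting-state functional connectivity. A within-subject
paired design (every subject scanned with both coils) makes the bias
directly measurable — and correctable with voxel-specific scaling factors.

`coilbias` implements that entire chain as tested, scriptable R code, with a
synthetic-data generator whose coil bias structure is known by construction,
so every stage can be validated against ground truth. All downstream stages
also accept real NIfTI-1 volumes.

## What is implemented

| Stage | Core idea |
|---|---|
| `make_tissue_phantom`, `make_coil_profile`, `simulate_t1/dwi/bold`, `make_cohort` | three-tissue nested-ellipsoid heads; parametric coil gain fields; Rician (magnitude) noise; paired multi-modality cohorts with injectable coil effects |
| `snr_map`, `snr_of_roi` | ROI-wise SNR from a signal and a noise-only image, `SNR = mean(signal) / (sqrt(2/(4-pi)) * SD(noise))` — the Rayleigh correction for magnitude-reconstructed noise |
| `estimate_bias`, `segment_tissues`, `smooth_gaussian` | registration-free VBM: polynomial log-intensity bias field, 3-class Gaussian-mixture EM segmentation (posteriors = partial volumes), mass-preserving smoothing (sigma 3 mm ≈ 7 mm FWHM) |
| `fit_tensor`, `fa_of_tensor`, `md_of_tensor`, `analysis_mask` | voxelwise OLS on `log S = log S0 − b gᵀDg`; closed-form symmetric eigenvalues; FA ≥ 0.2 analysis mask |
| `highpass`, `smooth_fwhm`, `dual_regression` | 0.01 Hz cosine/sine high-pass; 6 mm FWHM smoothing; two-stage dual regression with WM/CSF nuisance regressors, variance-normalized stage-2 design |
| `paired_t`, `tfce`, `permutation_fwe`, `summarize_effect` | paired t-maps; threshold-free cluster enhancement (H = 2, E = 0.5, 26-connectivity); sign-flip max-statistic permutation FWE (exact enumeration when `2^n ≤ n_perm`); paired Cohen's d and percent change |
| `split_cohort`, `estimate_scaling`, `apply_scaling`, `validate_harmonization` | age/sex-matched template/validation split; voxelwise 32CH/8CH ratio with 5 mm median filter; application and re-inference on held-out subjects |
| `run_experiment`, `experiment_config` | end-to-end orchestration with YAML configs, seeds and config-hash stamping |

TFCE, the permutation loop, separable convolution and the median filter are
implemented in C++ (Rcpp) so a 500-permutation run on a 32³ grid takes about
a second.

## Worked example

```r
library(coilbias)

report <- run_experiment(experiment_config(
  n_subjects = 6, seed = 2,
  cohort = cohort_config(modalities = "t1"),
  stats = list(n_perm = 200),
  harmonize = list(n_template = 3)))

subset(report$results, stage == "snr")[, c("metric", "value")]
#>                metric    value
#>     snr_8ch_anterior  39.42121
#>      snr_8ch_central  32.71040
#>    snr_8ch_posterior  32.11686
#>    snr_32ch_anterior  35.18378
#>     snr_32ch_central  37.78244
#>   snr_32ch_posterior  40.43569
```

The SNR block shows the two simulated coil signatures: the 8-channel coil is
~20% brighter anteriorly than centrally (frontal-high with a central drop),
while the 32-channel coil is flatter with its maximum posteriorly. The
`stats_gm` / `stats_wm` rows report FWE-significant voxel counts from the
paired TFCE permutation test on smoothed tissue maps (zero here — with no
injected contrast shift, bias correction removes the pure gain difference
before segmentation), and the `harmonize` rows compare significant-voxel
counts before and after applying the estimated scaling field to the held-out
validation subjects.

To see the mechanism the package is built around, inject a coil-dependent
contrast shift and watch GM and WM volume differences appear with opposite
signs at tissue boundaries:

```r
cfg <- cohort_config(modalities = "t1",
                     contrast_shift = c(eight_ch = 0, thirty_two_ch = 0.05))
# ... segment both coils per subject, then correlate the paired GM and WM
# difference maps on boundary voxels: strongly negative (about -0.99)
```

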