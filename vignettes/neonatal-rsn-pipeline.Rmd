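---
title: "Methods: neonatal resting-state network analysis with neorsn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal resting-state network analysis with neorsn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`neorsn` implements a complete group analysis of neonatal resting-state
fMRI: motion quality control by DVARS, group-level network definition by
temporally concatenated spatial ICA, projection to subject level by dual
regression, voxelwise general linear models with permutation/TFCE
family-wise error control, core-network-strength statistics, and a
winner-takes-all functional parcellation. All stages operate on 4D NIfTI-1
volumes that are already co-registered to a common voxel grid;
registration, distortion correction and ICA-based denoising of individual
runs are upstream concerns and out of scope.

The generative model assumed throughout is a linear mixture: subject $i$'s
data are

$$ y_i(v, t) = \sum_k a_{ik}\, m_k(v)\, s_{ik}(t) + \sum_j b_j(v)\, u_{ij}(t) + \varepsilon_i(v,t), $$

with shared network maps $m_k$, subject-specific low-frequency
(< 0.1 Hz) time courses $s_{ik}$, structured artifacts $b_j u_{ij}$ and
sensor noise. Covariates act on the amplitudes $a_{ik}$: a linear effect
of postmenstrual age (PMA) at scan, a multiplicative attenuation in
preterm-born infants, and a spatially restricted additive sex effect. The
synthetic-cohort generator (`simulate_cohort()`) emits exactly this model
with known parameters, so every downstream stage is testable by parameter
recovery.

## Motion QC

DVARS is the root-mean-square intensity difference between successive
volumes; the first volume has no predecessor and its DVARS is defined as 0
and never flagged. Volumes whose DVARS exceeds Q3 + 1.5 IQR of the
subject's own distribution (quartiles over volumes 2..T, estimated by the
common sorted-data linear-interpolation rule, quantile type 7) are motion
outliers. The contiguous window containing ~70% of the run (1600 of 2300
volumes at the target acquisition; `round(1600/2300 * T)` otherwise) with
the fewest outliers is retained, ties resolved toward the earliest start.
Subjects with strictly more than 10% outliers inside the window
(floor-rounded: more than 160 of 1600) are excluded entirely; the
in-window outlier count of retained subjects enters every later
regression as a nuisance covariate. The window search is exhaustive (a
cumulative-sum scan), and tests pin it to a brute-force oracle.

## Group ICA

Each subject's voxel time series is demeaned and variance-normalised over
time, subjects are concatenated along time, and the stack is reduced to K
dimensions by SVD with unit-variance whitening. Spatial independent
components are then estimated by the fixed-point algorithm with the
hyperbolic-tangent contrast and symmetric decorrelation (tolerance 1e-6,
at most 1000 iterations). Two behaviours deserve note:

* **Convergence.** When the data contain fewer genuinely non-Gaussian
  sources than K, the surplus directions span a near-Gaussian subspace in
  which the fixed-point update has no stable direction, and the iteration
  cannot reach tolerance. The default is an error with restart guidance;
  `on_nonconvergence = "warn"` returns the iterate with the smallest
  update step, which is the right behaviour for noise-calibration runs
  where weak-contrast components are expected by construction.
* **Z calibration.** Raw maps are converted to Z by centring on the map
  median and dividing by 1.4826 x MAD of the map. Because a component map
  is mostly background (non-network) voxels, this robust scale estimates
  the residual-noise standard deviation of the map; on sparse maps where
  the MAD degenerates to zero the ordinary standard deviation is used.
  This preserves the Z > 3 (core) and Z > 1 (parcellation) thresholding
  semantics without fitting a full Gaussian/Gamma mixture model. On
  pure-noise input about 0.3% of voxels exceed |Z| = 3, comfortably
  within the 1% calibration bound the tests assert.

Map sign follows positive skewness (networks are positive activations),
ordering follows explained variance, and signal/noise labels are the
analyst's: `label_components()` attaches them from a vector or TSV, with
`suggest_labels()` offering an edge-fraction and high-frequency-power
heuristic as a screening aid only.

A practical hazard deserves its own paragraph. Whole-volume intensity
shifts (motion spikes, global physiology) concentrate into a spatially
near-constant component, and spatial regression demeans maps over voxels:
the near-constant map collapses to a tiny-norm regressor that the other
maps jointly reconstruct, inflating the variance of every stage-1 time
course by two orders of magnitude (variance inflation factors of several
hundred were observed at desk scale). Such a component is simply
unidentifiable as a spatial regressor. `prune_components()` screens the
demeaned maps by variance inflation factor (default ceiling 10) and
removes offenders before dual regression; the workflow applies it right
after the ICA fit.

## Dual regression

Stage 1 regresses all group maps (signal and noise together, so artifact
components absorb confound variance) as spatial regressors into each
volume, after demeaning maps over voxels and each volume over voxels;
stage 2 regresses the resulting time courses, demeaned over time, into
each voxel's demeaned time series. Variance normalisation of the stage-1
time courses is a flag (`variance_normalise`, default off). The choice
matters scientifically: without it, amplitude lives in the time courses
and the beta maps encode shape only; with it, betas are in units of
response per unit time-course standard deviation and carry network
amplitude. Amplitude-sensitive analyses (core network strength, the
acceptance checks) therefore run with the flag on, and the workflow
config pins it explicitly.

## Voxelwise inference

Designs follow the study's covariate sets (age model on term-born
subjects with sex and motion; sex model with PMA, GA and motion; group
and GA-continuous models with PMA, sex and motion; weekly-bin group-mean
model with sex and motion). Continuous covariates are mean-centred; sex
is coded female = 1 and group preterm = 1. TFCE uses E = 0.5, H = 2, 100
integration steps and 26-connectivity, the standard volumetric defaults;
the integration's top threshold is clamped to the map maximum so the peak
voxel is never lost to floating-point rounding of `step * dh` (a genuine
failure mode the oracle tests caught). FWE control is by the permutation
max-statistic method under Freedman-Lane: data are residualised against
the nuisance columns, residual rows permuted, the nuisance fit added
back, and the full model refit. Two-tailed contrasts are two one-sided
max-TFCE tests, each against alpha = 0.025, with optional Bonferroni
division by the number of networks; weekly-bin maps use 0.05. Sampled
permutations are distinct and non-identity with
p = (1 + #{null >= obs}) / (1 + n_perm); when fewer distinct permutations
exist than requested, all n! are enumerated and p-values are exact
multiples of 1/n!. Weekly bins are half-open [lo, hi) — the printed bin
notation is ambiguous at shared endpoints and a convention had to be
fixed — and each bin takes the configured number of subjects with the
lowest postnatal age, ties by subject id.

## Core network strength and parcellation

Core network strength is the mean stage-2 beta over the network's group
template thresholded at Z > 3 (strict). Its analyses: partial Spearman
correlation with PMA at scan in term-born subjects controlling sex and
motion (average ranks for ties; residualise ranked quantities on ranked
covariates; p from the t approximation with n - c - 2 degrees of
freedom — an exact permutation p would also be defensible, the
approximation is standard and labelled); a per-network OLS of strength on
group, PMA, sex and motion; and percent reduction
100 (mean_term - mean_preterm) / mean_term on raw strengths, with an
unpaired Welch t-test. Degenerate inputs are handled explicitly: a
fully-residualised rank vector yields rho = 0, constant strengths yield
an NA t-test rather than an error, and a non-positive term mean is
flagged, not fatal.

The parcellation smooths each signal Z-map with a separable Gaussian
kernel (FWHM default 3 mm, about 1.5 voxels at 2.15 mm resolution; kernel
truncated at 3 sigma and renormalised at volume edges) and assigns each
voxel to the component with the largest smoothed Z among those strictly
above 1, ties to the lowest component index, 0 where no component
qualifies.

## The synthetic cohort: what it does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
smooth, non-negative, midline-symmetric network maps with pairwise
spatial correlation below 0.2 (mirrored Gaussian blob pairs,
max-normalised); band-limited unit-variance time courses (white noise
restricted to Fourier bins below 0.1 Hz — at very short runs at least two
non-DC bins are kept so the course is non-degenerate); deterministic
amplitude laws (base + slope x (PMA - 40), times (1 - attenuation) for
preterm subjects; an additive delta on the right-of-midline half of one
network's support for female subjects); edge-ring artifacts with
broadband time courses; iid Gaussian noise; and motion spikes as additive
whole-volume intensity jumps (QC consumes only DVARS, so rigid-body motion
itself is not simulated). The automatic spike amplitude is a clear
multiple of the DVARS noise floor (4 x noise SD plus half the peak network
amplitude): large enough that every spike crosses the outlier threshold,
small enough to stay on the scale of physiological intensity transients —
sizing spikes to the total signal amplitude instead makes residual
in-window spikes dominate the dual-regression betas through chance
correlations with the component time courses, a failure mode worth
avoiding deliberately.
Covariates are drawn from the study-population windows: PMA at scan
uniform on [37, 43.5] weeks; GA at birth uniform on [24.3, 36.9] for
preterm and on [37, min(42.3, PMA)] for term subjects, the upper clamp
enforcing that a scan cannot precede birth.

It does not emulate haemodynamics, cardiorespiratory spectra, multiband
slice artifacts, spatially varying noise, registration error or
between-subject map variability. Passing recovery tests therefore shows
the estimators are correct under the assumed model at realistic
signal-to-noise, not that the pipeline is robust to every property of
real data.

Default effect sizes are config-exposed package choices, calibrated so
that cohorts at the recovery-check scale are well powered (which is what
a recovery test must assume to be informative): base amplitude 1, age
slope 0.12 amplitude units per week on the age-carrying networks (a ~12%
amplitude change per week — steep, but of a piece with the rapid
maturation of functional connectivity around term-equivalent age),
preterm attenuation 0.30, noise SD 1. The slope is a joint calibration:
large enough that the age contrast is detected reliably at 56-60 term
subjects and 500 permutations, and no larger, because the slope itself
feeds back into the variance of the percent-reduction estimator (network
amplitude then varies strongly across subjects, and finite-sample
imbalance in age-at-scan between groups propagates into the raw group
means the estimator uses).

Residual in-window motion spikes — up to 10% of volumes are legitimately
retained by the exclusion rule — contribute a shared per-subject noise
term to the dual-regression betas (a spike is global, so its chance
correlation with a component time course shifts that subject's whole
beta map). This makes per-network percent-reduction estimates scatter by
a few points around the generative value, exactly as per-network values
scatter in real cohorts; the pooled cross-network mean is the estimator
of the single attenuation parameter and is what the recovery checks
hold to ±5 points.

One recovery subtlety: stage-1 time courses estimate a_k s_k plus
regression noise, so variance-normalised betas scale with
sqrt(a_k^2 + sigma_tc^2) rather than a_k exactly. The induced bias
shrinks the estimated preterm reduction by roughly one percentage point
at the default signal-to-noise — visible, bounded, and well inside the
±5-point recovery band the tests assert.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
a package choice balancing statistical resolution against runtime:
QC worked examples on full-length 2300-volume runs over small grids;
ICA recovery on 6-source mixtures across 10 seeds and a 30-component fit
on a 30-source cohort; null calibration of the FWE procedure on 200
(tests) or 100 (script) pure-noise cohorts of 20 subjects on a 12x12x8
grid at 200 permutations; effect recovery on cohorts of 60 term + 40
preterm subjects on a 16x16x12 grid, 120 volumes, 500 permutations, 20
(tests) or 10 (script) seeds. The recovery grid is the smallest at which
each network carries enough voxel mass that stage-1 time-course SNR
stays near 10:1 — on a much smaller grid the variance-normalised betas
acquire a visible compression bias in the term/preterm ratio (see the
recovery subtlety above), which is a property of the miniature, not of
the method. ICA recovery fixtures use disjoint
indicator-ball ("plateau") sources: because the concatenation step
variance-normalises every voxel, smooth blobs are reshaped into their
support indicators under noise-free mixing, and indicator sources are the
fixtures for which exact recovery is the correct expectation.

Other numerical decisions: whitening retains the top-K eigenvectors of
the temporal Gram matrix and rejects K above the numerical rank (relative
eigenvalue below 1e-12); the t-statistic's standard error is floored so
zero-residual voxels return t = 0 rather than NaN; per-subject and
per-stage seeds derive deterministically from one master seed and every
stage restores the caller's RNG state.

## Known limitations

* Manual component labelling is replaced in the automated workflow by
  matching to the generator's known truth; on real data the analyst's
  labels are required input.
* The robust-sigma Z calibration is a documented substitute for a
  mixture-model calibration; absolute Z levels can differ from
  mixture-calibrated maps, though thresholding behaviour is preserved.
* Exchangeability is assumed across all subjects in the permutation
  scheme; exchangeability blocks, variance smoothing and sign-flipping
  are not implemented.
* Each subject contributes one scan; nothing here models longitudinal
  dependence.
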