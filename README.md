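# neorsn

Group analysis of neonatal resting-state fMRI in R: from motion-aware
cropping of 4D BOLD runs to group networks, subject-level network maps,
permutation inference and functional parcellation — with a synthetic-cohort
generator that provides ground truth for every stage.

## Who this is for

Researchers analysing infant resting-state fMRI acquired around
term-equivalent age (roughly 37–44 weeks postmenstrual age, PMA), where the
scientific questions are: which resting-state networks (RSNs) are in place,
how does within-network functional connectivity change with age at scan,
does it differ by sex, and how is it altered by preterm birth. The package
assumes volumes already co-registered to a common grid; registration,
distortion correction and single-subject denoising live upstream.

## The model and the statistics

Subject data are treated as a linear mixture
`y_i(v,t) = Σ_k a_ik m_k(v) s_ik(t) + artifacts + noise`, with shared
spatial networks `m_k`, subject time courses `s_ik` (< 0.1 Hz) and
covariate-linked amplitudes `a_ik`. The pipeline:

1. **Motion QC** — DVARS (RMS intensity difference between successive
   volumes); outliers above Q3 + 1.5 IQR; crop to the contiguous ~70%
   window (1600 of 2300 volumes) with fewest outliers; exclude subjects
   with > 10% outliers in the window; carry the outlier count as a
   covariate everywhere downstream.
2. **Group ICA** — temporal concatenation, SVD whitening to K dimensions
   (study default K = 30), fixed-point spatial ICA (tanh contrast),
   robust-sigma Z-maps, analyst signal/noise labels.
3. **Dual regression** — stage 1: group maps as spatial regressors per
   volume → subject time courses; stage 2: those time courses as temporal
   regressors per voxel → subject β maps. Noise components ride along to
   absorb confound variance.
4. **Voxelwise GLM + permutation FWE** — study covariate sets per model;
   threshold-free cluster enhancement (E = 0.5, H = 2, 26-connectivity);
   Freedman–Lane permutation with the max-statistic method; two-tailed at
   p < 0.025 per direction, optional Bonferroni across networks;
   weekly-bin group maps at p < 0.05.
5. **Core network strength** — mean β inside the group template at Z > 3;
   partial Spearman vs PMA (controlling sex and motion), term-vs-preterm
   GLM (controlling PMA, sex, motion), percent reduction on raw strengths.
6. **Winner-takes-all parcellation** — smooth each network Z-map (3 mm
   FWHM), threshold at Z > 1, label each voxel by the winning network.

## Worked example

The repository is organised as an analysis workflow: numbered drivers under
`analysis/` run the whole study on a simulated cohort defined in
`analysis/config.yaml` (45 subjects: 30 term, 15 preterm; four networks,
two artifact components; a 0.12 amplitude-units/week age slope on networks
1–2; a 30% preterm attenuation; motion spikes at 4% of volumes):

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + ground truth
Rscript analysis/02_motion_qc.R         # DVARS, crop, exclusions
Rscript analysis/03_group_ica.R         # group networks + labels
Rscript analysis/04_dual_regression.R   # subject time courses + beta maps
Rscript analysis/05_voxel_inference.R   # TFCE permutation GLMs
Rscript analysis/06_network_strength.R  # core-strength statistics
Rscript analysis/07_parcellation.R      # winner-takes-all labels
```

A run prints, among other things:

```
[neorsn] cropped to 153 volumes; excluded 13 of 45 subjects; median outliers 13
[neorsn] pruning component IC01 (VIF 506)
[neorsn] matched correlations to true networks: 0.985, 0.980, 0.982, 0.981
[neorsn] age / IC04: 32 pos, 0 neg voxels at FWE p < 0.025
[neorsn] preterm_group / IC07: 0 pos, 17 neg voxels at FWE p < 0.025
[neorsn] age association IC04: partial rho = 0.542, p = 0.011
[neorsn] IC04: 30.6% reduction in preterm group (t = 2.18, p = 0.044)
[neorsn] IC07: 30.3% reduction in preterm group (t = 3.48, p = 0.0026)
[neorsn] parcellation: 1042 of 1568 voxels assigned; core agreement 100.0%
```

Reading these: the QC stage applied the ~70% crop and the >10% exclusion
rule to the simulated acquisition; a near-constant global component (the
signature of whole-volume motion spikes) was screened out before dual
regression; group ICA recovered all four generative networks at spatial
correlation ≈ 0.98; the age contrast finds suprathreshold voxels and a
positive strength–PMA partial correlation in a network carrying the
built-in age slope (IC04); preterm-born subjects show reduced connectivity
voxelwise and raw core-strength reductions of 25–31% against the
generative 30%; and the parcellation assigns every core network voxel to
the correct network. At this deliberately small cohort (23 term subjects
after QC) the second slope-carrying network shows the same signs without
reaching significance — the full-power behaviour is what the acceptance
checks verify at n = 60 + 40. Tables land in `results/` (QC report, GLM
summary, strength, associations, percent reduction, parcellation legend),
volumes under `scratch/`.

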