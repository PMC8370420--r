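# Desk-scale study configuration for the analysis workflow. One master seed
# drives every stage; per-stage seeds are derived from it.
seed: 20260922
cohort:
  grid: [14, 14, 8]
  T: 220
  tr: 0.392
  K_signal: 4
  K_artifact: 2
  n_term: 30
  n_preterm: 15
  base_amplitude: 1.0
  age_slope: [0.12, 0.12, 0.0, 0.0]
  preterm_attenuation: 0.30
  sex_effect: {network: 1, delta: 0.2}
  spike_rate: 0.04
  noise_sd: 1.0
qc:
  window_frac: 0.6956522   # 1600 / 2300
  exclude_frac: 0.10
ica:
  dim: 7
  seed_offset: 301
dual_regression:
  variance_normalise: true
inference:
  n_perm: 300
  alpha: 0.025
strength:
  z_thr: 3.0
parcellation:
  fwhm_mm: 3.0
  z_thr: 1.0
paths:
  scratch: scratch/analysis
  results: results
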