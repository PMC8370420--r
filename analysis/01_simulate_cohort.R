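#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic cohort. 45 subjects (30 term, 15 preterm)
# with 4 shared networks, 2 edge artifacts, a positive age slope on
# networks 1-2, a 30% preterm attenuation and DVARS-detectable motion
# spikes. Writes per-subject NIfTI volumes, the covariate TSV and the
# ground-truth record.

source("analysis/00_common.R")

nr_log("simulating cohort: %d term + %d preterm, grid %s, T = %d",
       cohort_cfg$n_term, cohort_cfg$n_preterm,
       paste(cohort_cfg$grid, collapse = "x"), cohort_cfg$T)

cohort <- simulate_cohort(cohort_cfg, dir = cohort_dir)

nr_log("wrote %d subject volumes under %s", nrow(cohort$metas), cohort_dir)
nr_log("true amplitude range: %.3f - %.3f",
       min(cohort$true_amplitudes), max(cohort$true_amplitudes))

write_stage_manifest("01_simulate", cohort_cfg$seed,
                     inputs = cfg_file,
                     outputs = c(cohort$paths$covariates,
                                 cohort$paths$truth))
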