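# Shared setup for the numbered analysis scripts: configuration, paths and
# the synthetic-cohort definition. Each driver sources this file.

library(neorsn)

cfg_file <- "analysis/config.yaml"
conf <- read_config(cfg_file)

scratch_dir <- conf$paths$scratch
results_dir <- conf$paths$results
dir.create(scratch_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

cohort_cfg <- with(conf$cohort, synth_config(
    grid = unlist(grid), T = T, tr = tr,
    K_signal = K_signal, K_artifact = K_artifact,
    n_term = n_term, n_preterm = n_preterm,
    base_amplitude = base_amplitude,
    age_slope = unlist(age_slope),
    preterm_attenuation = preterm_attenuation,
    sex_effect = sex_effect,
    spike_rate = spike_rate, noise_sd = noise_sd,
    seed = conf$seed))

cohort_dir <- file.path(scratch_dir, "cohort")

write_stage_manifest <- function(stage, seed, inputs = character(),
                                 outputs = character()) {
    m <- manifest_start(conf, conf$seed)
    m <- manifest_add_stage(m, stage, seed = seed, inputs = inputs,
                            outputs = outputs)
    dir.create(file.path(results_dir, "manifests"), showWarnings = FALSE,
               recursive = TRUE)
    manifest_write(m, file.path(results_dir, "manifests",
                                paste0(stage, ".json")))
}
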