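#!/usr/bin/env Rscript
# Stage 4: dual regression. All components (signal and noise alike) are
# regressed into each subject's cropped run: stage 1 gives per-component
# time courses, stage 2 gives per-component beta maps. Stage-1 time courses
# are variance-normalised before stage 2 so that betas carry network
# amplitude.

source("analysis/00_common.R")

metas <- read_covariates(file.path(results_dir, "covariates_qc.tsv"))
g <- readRDS(file.path(scratch_dir, "group_maps.rds"))
crop_dir <- file.path(scratch_dir, "cropped")
dr_dir <- file.path(scratch_dir, "dual_regression")
dir.create(dr_dir, showWarnings = FALSE)

drs <- vector("list", nrow(metas))
for (i in seq_len(nrow(metas))) {
    id <- metas$subject_id[i]
    b <- read_bold(file.path(crop_dir, paste0(id, "_cropped.nii.gz")),
                   subject_id = id)
    drs[[i]] <- dual_regress(b, g,
        variance_normalise = isTRUE(conf$dual_regression$variance_normalise))
    write.table(drs[[i]]$timecourses,
                file.path(dr_dir, paste0(id, "_timecourses.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_volume(drs[[i]]$beta_maps,
                 file.path(dr_dir, paste0(id, "_betas.nii.gz")))
}
saveRDS(drs, file.path(scratch_dir, "dual_regression.rds"))

nr_log("dual regression complete for %d subjects (%d components each)",
       length(drs), g$K)

write_stage_manifest("04_dualreg", conf$seed,
                     inputs = file.path(results_dir, "covariates_qc.tsv"),
                     outputs = character())
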