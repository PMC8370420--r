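#!/usr/bin/env Rscript
# Stage 2: motion QC. Per subject: DVARS, Q3 + 1.5 IQR outlier flagging,
# selection of the contiguous ~70% window with fewest outliers, cropping,
# and exclusion of subjects with > 10% outliers inside the window. Writes
# the QC report, the QC-updated covariates (motion count filled) and the
# cropped volumes.

source("analysis/00_common.R")

metas <- read_covariates(file.path(cohort_dir, "covariates.tsv"))
crop_dir <- file.path(scratch_dir, "cropped")
dir.create(crop_dir, showWarnings = FALSE)

qcs <- vector("list", nrow(metas))
for (i in seq_len(nrow(metas))) {
    b <- read_bold(file.path(cohort_dir,
                             paste0(metas$subject_id[i], "_bold.nii.gz")),
                   subject_id = metas$subject_id[i])
    qcs[[i]] <- run_subject_qc(b, metas[i, ],
                               window_frac = conf$qc$window_frac,
                               exclude_frac = conf$qc$exclude_frac)
    if (!qcs[[i]]$excluded)
        write_bold(qcs[[i]]$bold,
                   file.path(crop_dir,
                             paste0(metas$subject_id[i], "_cropped.nii.gz")))
    metas[i, ] <- qcs[[i]]$meta
}

report <- qc_report(qcs)
write.table(report, file.path(results_dir, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_covariates(metas[!report$excluded, ],
                 file.path(results_dir, "covariates_qc.tsv"))

nr_log("cropped to %d volumes; excluded %d of %d subjects; median outliers %d",
       report$length[1], sum(report$excluded), nrow(report),
       as.integer(median(report$outlier_count)))

write_stage_manifest("02_qc", conf$seed,
                     inputs = file.path(cohort_dir, "covariates.tsv"),
                     outputs = c(file.path(results_dir, "qc_report.tsv"),
                                 file.path(results_dir, "covariates_qc.tsv")))
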