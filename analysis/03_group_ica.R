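#!/usr/bin/env Rscript
# Stage 3: group-level network definition. Temporal concatenation of the
# cropped runs, whitening to the configured dimensionality, fixed-point
# spatial ICA, heuristic label suggestions, and labelling. In this
# synthetic study the ground truth is known, so components are labelled
# signal/noise by matching against the true network maps (standing in for
# the analyst's manual classification); the heuristic suggestions are
# written alongside for comparison.

source("analysis/00_common.R")

metas <- read_covariates(file.path(results_dir, "covariates_qc.tsv"))
crop_dir <- file.path(scratch_dir, "cropped")
bolds <- lapply(metas$subject_id, function(id)
    read_bold(file.path(crop_dir, paste0(id, "_cropped.nii.gz")),
              subject_id = id))

K <- conf$ica$dim
w <- concat_and_whiten(bolds, K = K)
nr_log("whitened: %d dims over %d voxels, variance captured %.1f%%",
       K, w$nvox, 100 * sum(w$var_explained))

g <- NULL
for (try in 0:4) {
    g <- tryCatch(fit_group_ica(w, seed = derive_seed(conf$seed,
                                                      conf$ica$seed_offset + try)),
                  error = function(e) { nr_log("%s", conditionMessage(e)); NULL })
    if (!is.null(g)) break
}
if (is.null(g)) {
    nr_log("falling back to best non-converged iterate")
    g <- suppressWarnings(fit_group_ica(w, seed = derive_seed(conf$seed,
                                                              conf$ica$seed_offset),
                                        on_nonconvergence = "warn"))
}

# a near-constant global component (volume-wide intensity shifts) is
# unidentifiable as a spatial regressor; screen it out before labelling
g <- prune_components(g)

truth <- jsonlite::read_json(file.path(cohort_dir, "truth.json"))
true_maps <- read_bold(file.path(cohort_dir, "true_maps.nii.gz"),
                       subject_id = "truth")$data
m <- match_maps(g$maps, true_maps)
labels <- rep("noise", g$K)
labels[m$perm] <- "signal"
g <- label_components(g, labels)
nr_log("matched correlations to true networks: %s",
       paste(sprintf("%.3f", m$cor), collapse = ", "))

sugg <- suggest_labels(g)
sugg$assigned <- labels
write.table(sugg, file.path(results_dir, "ica_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_group_maps(g, file.path(scratch_dir, "group_maps.nii.gz"),
                 file.path(results_dir, "ica_component_labels.tsv"))
saveRDS(g, file.path(scratch_dir, "group_maps.rds"))

write_stage_manifest("03_ica", derive_seed(conf$seed, conf$ica$seed_offset),
                     inputs = file.path(results_dir, "covariates_qc.tsv"),
                     outputs = file.path(results_dir, "ica_labels.tsv"))
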