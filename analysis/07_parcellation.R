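#!/usr/bin/env Rscript
# Stage 7: winner-takes-all functional parcellation of the signal
# components: Gaussian smoothing, Z > 1 candidate threshold, per-voxel
# argmax. Writes the integer-label volume, the legend, and a summary of
# agreement with the generator's true network layout.

source("analysis/00_common.R")

g <- readRDS(file.path(scratch_dir, "group_maps.rds"))
parc <- winner_takes_all(g, smoothing_fwhm = conf$parcellation$fwhm_mm,
                         z_thr = conf$parcellation$z_thr)
write_parcellation(parc, file.path(scratch_dir, "parcellation.nii.gz"),
                   file.path(results_dir, "parcellation_legend.tsv"),
                   voxel_size = g$voxel_size)

true_maps <- read_bold(file.path(cohort_dir, "true_maps.nii.gz"),
                       subject_id = "truth")$data
K_true <- dim(true_maps)[4]
V <- prod(g$grid)
tm <- matrix(true_maps, V, K_true)
truth_lab <- max.col(tm, ties.method = "first")
core <- tm[cbind(seq_len(V), truth_lab)] > 0.5
# map parcel labels to true networks via the component matching
m <- match_maps(g$maps[, , , signal_components(g), drop = FALSE], true_maps)
relabel <- integer(length(signal_components(g)))
relabel[m$perm] <- seq_len(K_true)
pl <- as.vector(parc$labels)
agree <- mean(ifelse(pl[core] > 0, relabel[pl[core]], 0) == truth_lab[core])

summary <- data.frame(assigned_voxels = sum(pl > 0), total_voxels = V,
                      core_voxels = sum(core), core_agreement = agree)
write.table(summary, file.path(results_dir, "parcellation_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
nr_log("parcellation: %d of %d voxels assigned; core agreement %.1f%%",
       sum(pl > 0), V, 100 * agree)

write_stage_manifest("07_parcellate", conf$seed,
                     inputs = character(),
                     outputs = file.path(results_dir, "parcellation_summary.tsv"))
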