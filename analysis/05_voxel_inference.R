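#!/usr/bin/env Rscript
# Stage 5: cross-subject voxelwise inference on the dual-regression beta
# maps. Age model (term-born only; covariates sex + motion) and term-vs-
# preterm model (covariates PMA at scan, sex, motion), both with TFCE and
# Freedman-Lane permutation max-statistic FWE correction, two-tailed at
# alpha per direction, plus Bonferroni across networks.

source("analysis/00_common.R")

metas <- read_covariates(file.path(results_dir, "covariates_qc.tsv"))
g <- readRDS(file.path(scratch_dir, "group_maps.rds"))
drs <- readRDS(file.path(scratch_dir, "dual_regression.rds"))
sig <- signal_components(g)
n_perm <- conf$inference$n_perm
alpha <- conf$inference$alpha
term <- metas$group == "term"

stat_dir <- file.path(scratch_dir, "stats")
dir.create(stat_dir, showWarnings = FALSE)

rows <- list()
run_model <- function(model, rows) {
    sel <- if (model == "age") which(term) else seq_len(nrow(metas))
    design <- build_design(metas[sel, ], model)
    for (k in sig) {
        betas <- stack_betas(drs[sel], k)
        r <- permutation_fwe(betas, design, tfce_params(), n_perm = n_perm,
                             seed = derive_seed(conf$seed, 500 + k))
        write_volume(array(c(r$t_map, r$tfce_pos, 1 - r$p_fwe_pos,
                             1 - r$p_fwe_neg), c(dim(r$t_map), 4)),
                     file.path(stat_dir, sprintf("%s_%s_stats.nii.gz",
                                                 model, g$names[k])))
        th <- threshold_results(r, alpha = alpha)
        thb <- threshold_results(r, alpha = alpha, n_networks = length(sig),
                                 bonferroni = TRUE)
        rows[[paste(model, k)]] <- data.frame(
            model = model, network = g$names[k], n = length(sel),
            n_perm = r$n_perm, max_t = max(r$t_map), min_t = min(r$t_map),
            sig_pos = sum(th$pos), sig_neg = sum(th$neg),
            sig_pos_bonf = sum(thb$pos), sig_neg_bonf = sum(thb$neg))
        nr_log("%s / %s: %d pos, %d neg voxels at FWE p < %.3g",
               model, g$names[k], sum(th$pos), sum(th$neg), alpha)
    }
    rows
}
rows <- run_model("age", rows)
rows <- run_model("preterm_group", rows)

summary <- do.call(rbind, rows)
write.table(summary, file.path(results_dir, "glm_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_stage_manifest("05_glm", conf$seed,
                     inputs = file.path(results_dir, "covariates_qc.tsv"),
                     outputs = file.path(results_dir, "glm_summary.tsv"))
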