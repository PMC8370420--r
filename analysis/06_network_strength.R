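#!/usr/bin/env Rscript
# Stage 6: core network strength. Mean beta within the group template at
# Z > 3 per subject and network; partial Spearman association with PMA at
# scan in term-born subjects (controlling sex + motion); term-vs-preterm
# GLM controlling PMA, sex and motion; percent reduction on raw strengths.

source("analysis/00_common.R")

metas <- read_covariates(file.path(results_dir, "covariates_qc.tsv"))
g <- readRDS(file.path(scratch_dir, "group_maps.rds"))
drs <- readRDS(file.path(scratch_dir, "dual_regression.rds"))

st <- strength_table(drs, g, z_thr = conf$strength$z_thr)
write.table(st, file.path(results_dir, "core_strength.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

term_ids <- metas$subject_id[metas$group == "term"]
assoc <- strength_age_association(st[st$subject_id %in% term_ids, ],
                                  metas[metas$group == "term", ])
write.table(assoc, file.path(results_dir, "strength_age_association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(assoc)))
    nr_log("age association %s: partial rho = %.3f, p = %.2g",
           assoc$network[i], assoc$rho[i], assoc$p[i])

gg <- strength_group_glm(st, metas)
write.table(gg$tests, file.path(results_dir, "strength_group_glm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gg$adjusted, file.path(results_dir, "strength_adjusted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pr <- percent_reduction(st, metas)
write.table(pr, file.path(results_dir, "percent_reduction.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(pr)))
    nr_log("%s: %.1f%% reduction in preterm group (t = %.2f, p = %.2g)",
           pr$network[i], pr$percent_reduction[i], pr$t[i], pr$p[i])

write_stage_manifest("06_strength", conf$seed,
                     inputs = file.path(results_dir, "covariates_qc.tsv"),
                     outputs = c(file.path(results_dir, "core_strength.tsv"),
                                 file.path(results_dir, "percent_reduction.tsv")))
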