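#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
#
# Simulates a monozygotic-twin methylation cohort with the study design
# (6 discordant, 4 concordant, 7 healthy pairs; 10,000 probes), a 6-type
# leukocyte reference, composition-confounded probes, and 13 injected
# single-co-twin outliers, then writes the pipeline's input files.

suppressPackageStartupMessages(library(epioutliers))

out <- file.path("results", "cohort")
seed <- 20180307

ref <- generate_cell_reference(K = 6, n_reference_probes = 100, seed = seed)
cfg <- twin_sim_config(n_probes = 10000, n_outlier_probes = 13,
                       n_composition_probes = 500,
                       cell_reference = ref, seed = seed)
coh <- generate_cohort(cfg)
paths <- write_cohort(coh, out)
utils::write.table(
  data.frame(probe_id = rownames(ref), ref, check.names = FALSE),
  file.path(out, "cell_reference.csv"), sep = ",", quote = FALSE,
  row.names = FALSE)

message(sprintf("cohort: %d probes x %d samples (%d pairs)",
                nrow(coh$beta), ncol(coh$beta),
                length(unique(coh$sheet$pair_id))))
message(sprintf("injected outliers: %d (carriers: %s)",
                nrow(coh$truth$outliers),
                paste(sort(unique(coh$truth$outliers$carrier)),
                      collapse = ", ")))
message(sprintf("betas clipped at [0,1]: %d", coh$truth$clipped))
message("inputs written to ", out)
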