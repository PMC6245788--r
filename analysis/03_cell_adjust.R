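#!/usr/bin/env Rscript
# Stage 3: cell-composition estimation and average-cell adjustment.
#
# Estimates 6 leukocyte-type proportions per sample from the reference
# by constrained least squares, compares them to the simulator's truth,
# and removes the fitted composition effect from every probe.

suppressPackageStartupMessages(library(epioutliers))

dir <- file.path("results", "cohort")
beta_full <- read_beta_matrix(file.path(dir, "beta.tsv"))
beta <- read_beta_matrix(file.path("results", "beta_filtered.tsv"))
ref <- read_beta_matrix(file.path(dir, "cell_reference.csv"), delimiter = ",")

props <- estimate_cell_proportions(beta_full, ref)
utils::write.csv(data.frame(sample_id = rownames(props), props),
                 file.path("results", "cell_proportions.csv"),
                 row.names = FALSE)

truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
message(sprintf("estimated proportions: %d samples x %d types; sums in [%.3f, %.3f]",
                nrow(props), ncol(props), min(rowSums(props)),
                max(rowSums(props))))

adj <- adjust_for_cells(beta, props)
message(sprintf("adjusted %d probes; %d values clipped to [0,1]",
                nrow(adj), attr(adj, "clipped")))
write_beta_matrix(adj, file.path("results", "beta_adjusted.tsv"))
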