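#!/usr/bin/env Rscript
# Stage 5: validation against concordant and healthy pairs.
#
# Profiles every flagged probe in the 4 concordant and 7 healthy pairs
# and classifies each pair's pattern (normative / shared outlier /
# single-co-twin outlier). A candidate survives when no validation pair
# shows a single-co-twin extreme; shared-outlier pairs are reported as
# SNV-suspect but do not invalidate.

suppressPackageStartupMessages(library(epioutliers))

dir <- file.path("results", "cohort")
beta <- read_beta_matrix(file.path("results", "beta_filtered.tsv"))
sheet <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
st <- utils::read.delim(file.path("results", "scan_results.tsv"))
cands <- st[st$outlier, ]

prof <- profile_pairs(beta, sheet, cands$probe_id,
                      z_threshold = 3, shared_diff_threshold_pp = 5)
rep <- validate_candidates(cands, prof)

utils::write.table(prof, file.path("results", "pair_profiles.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rep, file.path("results", "validation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("validated %d/%d candidates (%d SNV-suspect)",
                sum(rep$validated), nrow(rep), sum(rep$snv_suspect)))
bad <- rep[!rep$validated, ]
if (nrow(bad) > 0)
  message("not validated (single-co-twin extreme in a validation pair): ",
          paste(bad$probe_id, collapse = ", "))
message("validation tables written to results/")
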