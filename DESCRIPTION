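Package: epioutliers
Title: Epigenetic Outlier Detection in Monozygotic Twin Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of epigenetic outlier profiles in
    DNA methylation data from disease-discordant monozygotic twin pairs.
    Implements the full analysis pipeline: probe quality-control filtering
    (detection p-values, sex chromosomes, missingness), reference-based
    leukocyte cell-composition estimation and average-cell beta adjustment,
    per-probe one-tailed variance F-tests between affected and healthy
    co-twins, Storey q-value false-discovery-rate correction, a
    methylation-range-difference filter, per-pair outlier attribution, and
    validation of candidate probes against concordant and healthy pairs.
    Includes a synthetic-cohort generator that emulates the twin study design
    (shared within-pair effects, cell-composition confounding, rare
    single-co-twin outlier deviations) with ground-truth manifests, so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
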