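#' Remove probes with poor detection quality
#'
#' A probe is dropped when its detection p-value exceeds `threshold` in at
#' least one sample (strictest reading: any failing sample disqualifies the
#' probe). The sample set is unchanged.
#'
#' @param beta probe-by-sample beta matrix.
#' @param detp matching detection p-value matrix.
#' @param threshold detection p-value cut-off, default 1e-4.
#' @return filtered beta matrix.
#' @export
filter_by_detection <- function(beta, detp, threshold = 1e-4) {
  if (!identical(dim(beta), dim(detp)) ||
      !identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp)))
    stop("detection-p matrix does not match the beta matrix", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("detection threshold must lie in (0, 1]", call. = FALSE)
  fails <- rowSums(detp > threshold, na.rm = TRUE) > 0
  beta[!fails, , drop = FALSE]
}

#' Keep only autosomal probes
#'
#' Removes probes annotated to chromosomes X or Y (sex-chromosome
#' methylation would confound a mixed-sex cohort). Probes missing from the
#' annotation are handled per `unannotated`: dropped with a warning
#' (default) or kept.
#'
#' @param beta probe-by-sample beta matrix.
#' @param annotation probe annotation with `probe_id` and `chromosome`.
#' @param unannotated "drop" (default) or "keep".
#' @return filtered beta matrix.
#' @export
filter_autosomes <- function(beta, annotation, unannotated = c("drop", "keep")) {
  unannotated <- match.arg(unannotated)
  chrom <- annotation$chromosome[match(rownames(beta), annotation$probe_id)]
  autosomal <- chrom %in% as.character(1:22)
  if (anyNA(chrom)) {
    n <- sum(is.na(chrom))
    if (unannotated == "drop") {
      warning(n, " unannotated probe(s) dropped")
    } else {
      autosomal[is.na(chrom)] <- TRUE
    }
  }
  beta[autosomal, , drop = FALSE]
}

#' Remove probes with missing values in the named samples
#'
#' Drops every probe carrying at least one missing value among `samples`.
#' The default sample set is the discordant-pair individuals — the group
#' whose variances are tested — so probes unusable for the scan are
#' removed while missingness confined to validation pairs is tolerated.
#'
#' @param beta probe-by-sample beta matrix.
#' @param samples sample ids to require completeness in; default all columns.
#' @return filtered beta matrix.
#' @export
filter_complete <- function(beta, samples = colnames(beta)) {
  unknown <- setdiff(samples, colnames(beta))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- rowSums(is.na(beta[, samples, drop = FALSE])) == 0
  beta[keep, , drop = FALSE]
}

#' Run the full probe-filtering funnel
#'
#' Applies, in order: detection-p filter, autosome filter, completeness
#' filter over the discordant-pair individuals. Returns the filtered matrix
#' together with a stage-by-stage `filter_report` whose counts reconcile
#' exactly (filters are sequential, so no probe is double-counted).
#'
#' @param beta probe-by-sample beta matrix.
#' @param sheet validated sample sheet (for the discordant individuals).
#' @param annotation probe annotation.
#' @param detp optional detection p-value matrix; stage skipped when NULL.
#' @param detection_threshold detection p cut-off, default 1e-4.
#' @return list with `beta` (filtered matrix) and `report` (filter_report).
#' @export
filter_probes <- function(beta, sheet, annotation, detp = NULL,
                          detection_threshold = 1e-4) {
  n0 <- nrow(beta)
  b1 <- if (is.null(detp)) beta else
    filter_by_detection(beta, detp, detection_threshold)
  b2 <- filter_autosomes(b1, annotation)
  disc <- discordant_samples(sheet)$all
  b3 <- filter_complete(b2, disc)
  report <- structure(list(
    input_probe_count = n0,
    removed_by_detection = n0 - nrow(b1),
    removed_sex_chromosomes = nrow(b1) - nrow(b2),
    removed_missing = nrow(b2) - nrow(b3),
    output_probe_count = nrow(b3)), class = "filter_report")
  list(beta = b3, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe-filtering funnel\n")
  cat(sprintf("  input probes:            %d\n", x$input_probe_count))
  cat(sprintf("  removed, detection p:    %d\n", x$removed_by_detection))
  cat(sprintf("  removed, chrX/chrY:      %d\n", x$removed_sex_chromosomes))
  cat(sprintf("  removed, missing values: %d\n", x$removed_missing))
  cat(sprintf("  probes retained:         %d\n", x$output_probe_count))
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param report a `filter_report`.
#' @param path output path for the JSON sidecar.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
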