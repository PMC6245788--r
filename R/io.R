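#' Read a beta-value matrix from delimited text
#'
#' First column holds probe ids, header row holds sample ids. Empty cells
#' and "NA" are read as missing. Values outside \[0, 1\] raise an error
#' naming the offending probe and sample; they are never clamped.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  read_value_matrix(path, delimiter, what = "beta")
}

#' Read a detection p-value matrix
#'
#' Same layout as [read_beta_matrix()]. When `beta` is supplied, the probe
#' and sample identifiers must match it exactly.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param beta optional companion beta matrix to cross-check dimensions.
#' @return validated numeric matrix of detection p-values.
#' @export
read_detection_p <- function(path, delimiter = "\t", beta = NULL) {
  detp <- read_value_matrix(path, delimiter, what = "detection p")
  if (!is.null(beta)) {
    if (!identical(rownames(detp), rownames(beta)) ||
        !identical(colnames(detp), colnames(beta)))
      stop("detection-p matrix identifiers do not match the beta matrix",
           call. = FALSE)
  }
  detp
}

read_value_matrix <- function(path, delimiter, what) {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2)
    stop(what, " matrix at '", path, "': need a probe column plus samples",
         call. = FALSE)
  probes <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  nonnum <- is.na(vals) & !is.na(as.matrix(df[-1]))
  if (any(nonnum)) {
    ij <- which(nonnum, arr.ind = TRUE)[1, ]
    stop(sprintf("%s matrix at '%s': non-numeric cell at probe '%s', sample '%s'",
                 what, path, probes[ij[1]], colnames(vals)[ij[2]]), call. = FALSE)
  }
  rownames(vals) <- probes
  beta_matrix(vals)
}

#' Read and validate a twin-cohort sample sheet
#'
#' CSV with columns `sample_id`, `pair_id`, `role`, `status`, optionally
#' `pair_class` and `sex`; see [validate_sample_sheet()] for the rules.
#'
#' @param path file path.
#' @return validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Read a probe annotation table
#'
#' CSV with columns `probe_id`, `chromosome` ("1".."22", "X", "Y"),
#' `position` (1-based, hg19 in the packaged data), and optionally
#' `gene_name` and `gene_region` (empty where a probe maps to no gene,
#' mirroring the "-" entries of published candidate tables).
#'
#' @param path file path.
#' @return validated annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  req <- c("probe_id", "chromosome", "position")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  allowed <- c(as.character(1:22), "X", "Y")
  if (!all(ann$chromosome %in% allowed))
    stop("annotation chromosome outside 1..22/X/Y: ",
         paste(unique(setdiff(ann$chromosome, allowed)), collapse = ", "),
         call. = FALSE)
  ann$position <- as.integer(ann$position)
  if (any(is.na(ann$position)) || any(ann$position < 1))
    stop("annotation positions must be integers >= 1", call. = FALSE)
  if (!"gene_name" %in% names(ann)) ann$gene_name <- ""
  if (!"gene_region" %in% names(ann)) ann$gene_region <- ""
  ann$gene_name[ann$gene_name %in% c("-", "NA")] <- ""
  ann$gene_region[ann$gene_region %in% c("-", "NA")] <- ""
  ann
}

#' Write a beta-value matrix as delimited text
#'
#' Missing entries are written as "NA". A read-write-read round trip
#' reproduces the matrix at the written precision (default 10 significant
#' digits, far below assay resolution).
#'
#' @param beta numeric probe-by-sample matrix.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @param digits significant digits written, default 10.
#' @export
write_beta_matrix <- function(beta, path, delimiter = "\t", digits = 10) {
  df <- data.frame(probe_id = rownames(beta),
                   signif(beta, digits), check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write per-probe scan statistics with annotation
#'
#' Produces the report table mirroring a published candidate-probe layout:
#' probe id, F statistic, degrees of freedom, one-tailed p, q, beta ranges
#' of both groups in percent, their difference in percentage points, the
#' mean methylation, the outlier flag, and genomic annotation. Rows are
#' sorted by q then p. Probes absent from the annotation get empty fields.
#'
#' @param stats data frame of per-probe statistics from [scan_outliers()].
#' @param annotation probe annotation data frame (or NULL).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(stats, annotation = NULL, path) {
  out <- stats[order(stats$q, stats$p), , drop = FALSE]
  if (!is.null(annotation)) {
    idx <- match(out$probe_id, annotation$probe_id)
    out$chromosome <- ifelse(is.na(idx), "", annotation$chromosome[idx])
    out$position <- annotation$position[idx]
    out$gene_name <- ifelse(is.na(idx), "", annotation$gene_name[idx])
    out$gene_region <- ifelse(is.na(idx), "", annotation$gene_region[idx])
  } else {
    out$chromosome <- ""
    out$position <- NA_integer_
    out$gene_name <- ""
    out$gene_region <- ""
  }
  cols <- c("probe_id", "F", "df1", "df2", "p", "q",
            "affected_range_pct", "healthy_range_pct", "range_diff_pp",
            "mean_beta", "outlier", "chromosome", "position",
            "gene_name", "gene_region")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export outlier probes as a BED file
#'
#' Converts 1-based probe positions to 0-based half-open single-base BED
#' intervals (start = position - 1, end = position). The score column
#' carries -log10(q), capped at 1000.
#'
#' @param stats per-probe statistics; only rows with `outlier == TRUE` are
#'   exported.
#' @param annotation probe annotation supplying chromosome and position;
#'   probes without annotation are skipped with a warning.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_bed <- function(stats, annotation, path) {
  hits <- stats[isTRUE_vec(stats$outlier), , drop = FALSE]
  idx <- match(hits$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    warning("outlier probes without annotation skipped in BED export: ",
            paste(hits$probe_id[is.na(idx)], collapse = ", "))
    hits <- hits[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(hits) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = paste0("chr", annotation$chromosome[idx]),
    start = annotation$position[idx] - 1L,
    end = annotation$position[idx],
    name = hits$probe_id,
    score = pmin(1000, round(-log10(pmax(hits$q, 1e-300)), 2)))
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Published candidate probes from the GSE120307 twin cohort
#'
#' Loads the packaged table of the thirteen CpG probes reported with
#' epigenetic-outlier methylation in affected co-twins of
#' depression-discordant monozygotic pairs (GEO SuperSeries GSE120307):
#' unadjusted p, q, group beta ranges (%), printed range difference (pp),
#' mean methylation (%), hg19 coordinates and gene annotation.
#'
#' @return data frame with one row per candidate probe.
#' @export
published_candidates <- function() {
  path <- system.file("extdata", "gse120307_candidates.tsv",
                      package = "epioutliers", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
}
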