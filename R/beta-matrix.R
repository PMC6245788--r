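#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with
#' probes as rows and samples as columns. Probe and sample identifiers live
#' in the dimnames. Values are fractions in \[0, 1\]; `NA` entries are
#' permitted until the missingness filter has run.
#'
#' @param values numeric matrix; rownames are probe ids, colnames sample ids.
#' @return the validated matrix, invisibly unchanged.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix requires probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  values
}

#' Methylation fraction from fluorescence intensities
#'
#' Computes beta = M / (M + U + alpha), the methylation fraction of a CpG
#' site from its methylated (M) and unmethylated (U) channel intensities,
#' with a non-negative offset alpha stabilising low-intensity probes.
#'
#' @param M methylated intensity, non-negative (arbitrary units). Vectorised.
#' @param U unmethylated intensity, non-negative.
#' @param alpha stabilising offset, non-negative; the platform value is not
#'   standardised, so it must be given explicitly (commonly 100).
#' @return methylation fraction(s) in \[0, 1\].
#' @examples
#' compute_beta_from_intensities(300, 100, 100) # 0.6
#' @export
compute_beta_from_intensities <- function(M, U, alpha) {
  if (any(M < 0) || any(U < 0) || any(alpha < 0))
    stop("intensities and offset must be non-negative", call. = FALSE)
  tot <- M + U + alpha
  if (any(tot == 0))
    stop("undefined beta: M + U + alpha is zero", call. = FALSE)
  M / tot
}

#' Validate a sample sheet for a monozygotic-twin cohort
#'
#' Required columns: `sample_id`, `pair_id`, `role` (twin_a/twin_b),
#' `status` (affected/healthy), and optionally `pair_class`
#' (discordant/concordant/healthy) and `sex`. Every pair must have exactly
#' two members, one per role. `pair_class` is derived from the two statuses
#' when absent and cross-checked when present: a discordant pair has one
#' affected and one healthy co-twin, a concordant pair two affected, a
#' healthy pair two healthy.
#'
#' @param sheet data frame with the columns above.
#' @return the sheet with a validated `pair_class` column.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "pair_id", "role", "status")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  if (!all(sheet$role %in% c("twin_a", "twin_b")))
    stop("role must be twin_a or twin_b", call. = FALSE)
  if (!all(sheet$status %in% c("affected", "healthy")))
    stop("status must be affected or healthy", call. = FALSE)

  split_pairs <- split(sheet, sheet$pair_id)
  derived <- vapply(split_pairs, function(p) {
    if (nrow(p) != 2 || !setequal(p$role, c("twin_a", "twin_b")))
      stop("pair '", p$pair_id[1],
           "' must have exactly two members, one per role", call. = FALSE)
    n_aff <- sum(p$status == "affected")
    c("healthy", "discordant", "concordant")[n_aff + 1]
  }, character(1))

  if ("pair_class" %in% names(sheet)) {
    stated <- vapply(split_pairs, function(p) unique(p$pair_class)[1], character(1))
    bad <- names(derived)[stated != derived]
    if (length(bad))
      stop("pair_class contradicts member statuses for pair(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sheet$pair_class <- derived[as.character(sheet$pair_id)]
  if (!"sex" %in% names(sheet)) sheet$sex <- "unknown"
  sheet
}

#' Co-twins belonging to discordant pairs, split by status
#'
#' @param sheet validated sample sheet.
#' @return list with `affected` and `healthy` sample-id vectors and
#'   `all` (every discordant-pair individual).
#' @export
discordant_samples <- function(sheet) {
  d <- sheet[sheet$pair_class == "discordant", ]
  list(affected = d$sample_id[d$status == "affected"],
       healthy  = d$sample_id[d$status == "healthy"],
       all      = d$sample_id)
}
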