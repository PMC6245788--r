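#' Per-pair methylation profiles at candidate probes
#'
#' For each candidate probe and each pair of the requested classes,
#' records both co-twin betas, their intrapair difference in percentage
#' points, and the pair's pattern from [classify_pair_pattern()] computed
#' against all samples outside the pair. The long-format result is
#' directly plottable as per-pair line profiles.
#'
#' @param beta probe-by-sample beta matrix.
#' @param sheet validated sample sheet.
#' @param probes candidate probe ids (must be rows of `beta`).
#' @param pair_classes pair classes to profile, default
#'   `c("concordant", "healthy")` (the validation subsets).
#' @param z_threshold robust z cut-off passed to the classifier.
#' @param shared_diff_threshold_pp intrapair-difference cut-off (pp).
#' @return data frame with one row per (probe, pair): probe_id, pair_id,
#'   pair_class, value_a, value_b, intrapair_diff_pp, pattern.
#' @export
profile_pairs <- function(beta, sheet, probes,
                          pair_classes = c("concordant", "healthy"),
                          z_threshold = 3, shared_diff_threshold_pp = 5) {
  unknown <- setdiff(probes, rownames(beta))
  if (length(unknown))
    stop("unknown probe(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sel <- sheet[sheet$pair_class %in% pair_classes, ]
  pair_ids <- unique(sel$pair_id)
  if (!length(pair_ids))
    stop("no pairs of class ", paste(pair_classes, collapse = "/"),
         " in the sample sheet", call. = FALSE)
  rows <- lapply(probes, function(pr) {
    v <- beta[pr, ]
    do.call(rbind, lapply(pair_ids, function(pid) {
      members <- sheet[sheet$pair_id == pid, ]
      members <- members[order(members$role), ]  # twin_a first
      a <- unname(v[members$sample_id[1]])
      b <- unname(v[members$sample_id[2]])
      ref <- v[setdiff(names(v), members$sample_id)]
      data.frame(probe_id = pr, pair_id = pid,
                 pair_class = members$pair_class[1],
                 value_a = a, value_b = b,
                 intrapair_diff_pp = abs(a - b) * 100,
                 pattern = classify_pair_pattern(
                   a, b, ref, z_threshold, shared_diff_threshold_pp),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a twin pair's methylation pattern at one probe
#'
#' A co-twin is "outlying" when its robust z-score against the reference
#' samples — (value - median) / (1.4826 x MAD) — exceeds `z_threshold` in
#' absolute value. The pair pattern is:
#' \describe{
#'   \item{shared_outlier}{both co-twins outlying and within
#'     `shared_diff_threshold_pp` of each other — the SNV-like or
#'     shared-exposure signature where a pair sits apart from the cohort
#'     with near-identical values;}
#'   \item{discordant_outlier}{exactly one co-twin outlying — the
#'     disease-linked single-co-twin signature;}
#'   \item{normative}{otherwise.}
#' }
#' When the reference MAD is zero the z-score is undefined; the
#' classifier falls back to a range rule (outlying = outside the
#' reference \[min, max\] by more than `shared_diff_threshold_pp` pp).
#'
#' @param value_a,value_b co-twin betas.
#' @param reference_values betas of all samples outside the pair at the
#'   probe; at least 4 required.
#' @param z_threshold robust z cut-off, default 3.
#' @param shared_diff_threshold_pp intrapair-difference cut-off in
#'   percentage points, default 5 (intrapair differences below ~5 pp are
#'   within technical measurement noise).
#' @return one of "normative", "shared_outlier", "discordant_outlier".
#' @export
classify_pair_pattern <- function(value_a, value_b, reference_values,
                                  z_threshold = 3,
                                  shared_diff_threshold_pp = 5) {
  if (length(reference_values) < 4)
    stop("need at least 4 reference values", call. = FALSE)
  med <- stats::median(reference_values)
  s <- stats::mad(reference_values)  # 1.4826 * MAD
  if (s > 0) {
    out_a <- abs(value_a - med) / s > z_threshold
    out_b <- abs(value_b - med) / s > z_threshold
  } else {
    margin <- shared_diff_threshold_pp / 100
    lo <- min(reference_values); hi <- max(reference_values)
    out_a <- value_a < lo - margin | value_a > hi + margin
    out_b <- value_b < lo - margin | value_b > hi + margin
  }
  if (out_a && out_b &&
      abs(value_a - value_b) * 100 < shared_diff_threshold_pp)
    return("shared_outlier")
  if (xor(out_a, out_b)) return("discordant_outlier")
  "normative"
}

#' Validate candidate probes against concordant and healthy pairs
#'
#' A candidate survives validation when no validation pair shows a
#' discordant-outlier (single-co-twin extreme) pattern at that probe:
#' such a pattern in unaffected pairs would mark the original signal as a
#' technical artifact or a disease-unrelated epigenetic event. Shared-
#' outlier pairs — both co-twins extreme with near-identical values — do
#' not invalidate; they indicate sequence-variant-driven or
#' shared-exposure methylation and are reported as an SNV-suspect
#' annotation.
#'
#' @param candidates per-probe statistics of flagged probes (rows with
#'   `outlier = TRUE` of a [scan_outliers()] result, or any data frame
#'   with a `probe_id` column).
#' @param profiles pair profiles from [profile_pairs()] covering every
#'   candidate probe.
#' @return data frame per candidate: probe_id, n_pairs, n_shared_outlier,
#'   n_discordant_outlier, snv_suspect, validated.
#' @export
validate_candidates <- function(candidates, profiles) {
  probes <- unique(candidates$probe_id)
  missing <- setdiff(probes, unique(profiles$probe_id))
  if (length(missing))
    stop("profiles missing for candidate probe(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!length(probes))
    return(data.frame(probe_id = character(0), n_pairs = integer(0),
                      n_shared_outlier = integer(0),
                      n_discordant_outlier = integer(0),
                      snv_suspect = logical(0), validated = logical(0)))
  out <- do.call(rbind, lapply(probes, function(pr) {
    pp <- profiles[profiles$probe_id == pr, ]
    n_shared <- sum(pp$pattern == "shared_outlier")
    n_disc <- sum(pp$pattern == "discordant_outlier")
    data.frame(probe_id = pr, n_pairs = nrow(pp),
               n_shared_outlier = n_shared,
               n_discordant_outlier = n_disc,
               snv_suspect = n_shared > 0,
               validated = n_disc == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
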