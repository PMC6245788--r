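#' Genome-wide one-tailed variance scan over discordant pairs
#'
#' For every probe, compares the variance of the affected co-twins against
#' the healthy co-twins of the discordant pairs with the one-tailed F-test
#' ([variance_f_test()]), adjusts all p-values with Storey q-values, and
#' applies the two-stage outlier rule: a probe is an outlier when
#' `q <= q_threshold` AND the affected group's beta range exceeds the
#' healthy group's by strictly more than `range_threshold_pp` percentage
#' points. Significant probes failing the range stage are retained in the
#' table (`outlier = FALSE`) so the funnel — tested, significant,
#' range-filtered — is fully inspectable.
#'
#' The groups are treated as independent samples of the two diagnostic
#' conditions; twin pairing is not modelled in the test itself (each group
#' holds one member of every pair, so shared pair effects cancel between
#' the two variances in expectation).
#'
#' @param beta probe-by-sample beta matrix, filtered (no missing values
#'   among discordant-pair individuals) and optionally cell-adjusted.
#' @param sheet validated sample sheet with >= 2 discordant pairs.
#' @param q_threshold significance cut-off on q, default 0.05.
#' @param range_threshold_pp range-difference cut-off in percentage
#'   points, default 10 (strict inequality).
#' @return data frame of per-probe statistics (probe_id, F, df1, df2, p,
#'   q, affected_range_pct, healthy_range_pct, range_diff_pp, mean_beta,
#'   outlier) with attributes `pi0`, `funnel` (tested / significant /
#'   outliers / degenerate counts).
#' @export
scan_outliers <- function(beta, sheet, q_threshold = 0.05,
                          range_threshold_pp = 10) {
  grp <- discordant_samples(sheet)
  if (length(grp$affected) < 2 || length(grp$healthy) < 2)
    stop("need at least two affected and two healthy discordant co-twins",
         call. = FALSE)
  X <- beta[, grp$affected, drop = FALSE]
  Y <- beta[, grp$healthy, drop = FALSE]
  if (anyNA(X) || anyNA(Y))
    stop("missing values among discordant-pair samples; run filter_complete ",
         "before scanning", call. = FALSE)
  n <- ncol(X); m <- ncol(Y)
  s2x <- row_vars(X)
  s2y <- row_vars(Y)
  Fstat <- ifelse(s2y > 0, s2x / s2y, ifelse(s2x > 0, Inf, NaN))
  p <- ifelse(s2y > 0, stats::pf(s2x / pmax(s2y, .Machine$double.xmin),
                                 n - 1, m - 1, lower.tail = FALSE),
              ifelse(s2x > 0, 0, 1))
  degenerate <- s2x == 0 & s2y == 0
  qres <- storey_qvalues(p)
  aff_range <- (row_max(X) - row_min(X)) * 100
  hea_range <- (row_max(Y) - row_min(Y)) * 100
  range_diff <- aff_range - hea_range
  outlier <- qres$qvalues <= q_threshold & range_diff > range_threshold_pp
  stats <- data.frame(
    probe_id = rownames(beta),
    F = Fstat, df1 = n - 1L, df2 = m - 1L,
    p = p, q = qres$qvalues,
    affected_range_pct = aff_range,
    healthy_range_pct = hea_range,
    range_diff_pp = range_diff,
    mean_beta = rowMeans(cbind(X, Y)),
    outlier = outlier,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(stats, "pi0") <- qres$pi0
  attr(stats, "funnel") <- list(
    tested = nrow(stats),
    significant = sum(qres$qvalues <= q_threshold),
    range_filtered = sum(qres$qvalues <= q_threshold & range_diff <= range_threshold_pp),
    outliers = sum(outlier),
    degenerate = sum(degenerate))
  stats
}

row_vars <- function(x) {
  rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
}

row_max <- function(x) do.call(pmax, as.data.frame(x))
row_min <- function(x) do.call(pmin, as.data.frame(x))

#' Attribute an outlier probe to the deviant affected co-twin
#'
#' At a flagged probe, identifies which affected co-twin carries the
#' outlying methylation value: the affected sample with maximum absolute
#' deviation from the median of all discordant-pair samples at that
#' probe. Ties break to the lexicographically first sample id and are
#' flagged.
#'
#' @param values named vector of betas for the discordant-pair samples at
#'   one probe (names are sample ids).
#' @param sheet validated sample sheet.
#' @return list with `pair_id`, `sample_id`, `deviation_pp` (percentage
#'   points from the discordant-cohort median) and `tie`.
#' @export
identify_outlier_cotwin <- function(values, sheet) {
  grp <- discordant_samples(sheet)
  med <- stats::median(values[grp$all])
  dev_pp <- abs(values[grp$affected] - med) * 100
  ord <- order(-dev_pp, names(dev_pp))
  top <- names(dev_pp)[ord[1]]
  tie <- sum(dev_pp == dev_pp[ord[1]]) > 1
  list(pair_id = sheet$pair_id[match(top, sheet$sample_id)],
       sample_id = top,
       deviation_pp = unname(dev_pp[ord[1]]),
       tie = tie)
}
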