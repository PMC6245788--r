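#' One-tailed F-test for excess variance in the affected group
#'
#' Tests whether the affected co-twins are more variable than the healthy
#' co-twins at one probe. The statistic is the ratio of unbiased sample
#' variances F = S2_affected / S2_healthy — the affected group is always
#' the numerator — referred to the upper tail of the F distribution with
#' (n - 1, m - 1) degrees of freedom. Only excess variance in the affected
#' group can reach significance; probes where the healthy group is the
#' more variable one get p > 0.5.
#'
#' Degenerate probes never abort a genome-scale scan: a zero healthy
#' variance with positive affected variance yields `F = Inf`, `p = 0`;
#' both variances zero yields `F = NaN`, `p = 1` with `degenerate = TRUE`.
#'
#' @param affected numeric vector of affected-group betas, length >= 2.
#' @param healthy numeric vector of healthy-group betas, length >= 2.
#' @return list with `F`, `df1`, `df2`, `p`, `degenerate`.
#' @examples
#' x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
#' variance_f_test(x, x)$p  # 0.5 at equal degrees of freedom
#' @export
variance_f_test <- function(affected, healthy) {
  n <- length(affected); m <- length(healthy)
  if (n < 2 || m < 2)
    stop("each group needs at least two observations", call. = FALSE)
  s2x <- stats::var(affected)
  s2y <- stats::var(healthy)
  df1 <- n - 1L; df2 <- m - 1L
  if (s2y == 0) {
    if (s2x == 0)
      return(list(F = NaN, df1 = df1, df2 = df2, p = 1, degenerate = TRUE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = FALSE))
  }
  Fstat <- s2x / s2y
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Methylation range of a group, in percent
#'
#' @param values numeric vector of betas, length >= 1.
#' @return (max - min) x 100, in percentage points.
#' @export
beta_range <- function(values) {
  if (length(values) < 1) stop("empty group", call. = FALSE)
  (max(values) - min(values)) * 100
}
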