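#' Storey q-values with smoother-based pi0 estimation
#'
#' Computes false-discovery-rate q-values. The null proportion pi0 is
#' estimated on the lambda grid 0.05, 0.10, ..., 0.95 as
#' `#\{p > lambda\} / (m (1 - lambda))`, smoothed with a cubic smoothing
#' spline (3 df) and evaluated at the largest lambda, then truncated to
#' (0, 1]. q-values follow the step-up rule
#' `q_(i) = min_{j >= i} pi0 m p_(j) / j`, reported in the original order
#' and clamped to \[0, 1\]; they are monotone in p by construction.
#'
#' For vectors shorter than the lambda grid (fewer than 20 p-values) the
#' smoother is unreliable and pi0 falls back to 1 with a warning, making
#' the q-values equal to Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param pi0 optional fixed null proportion overriding estimation (e.g.
#'   `pi0 = 1` for plain Benjamini-Hochberg behaviour).
#' @return list with `qvalues` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (length(p) < 1) stop("need at least one p-value", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}

estimate_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  m <- length(p)
  if (m < 20) {
    warning("fewer than 20 p-values: pi0 set to 1")
    return(1)
  }
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}
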