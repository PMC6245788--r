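#' Estimate leukocyte-type proportions by constrained least squares
#'
#' Reference-based deconvolution: for each sample, finds the non-negative
#' cell-type proportion vector, summing to at most one, that minimises the
#' squared deviation between the sample's betas at the discriminating
#' reference probes and the proportion-weighted combination of the
#' reference profiles. Any shortfall from one is the unmodelled remainder
#' (e.g. granulocyte contamination outside the reference panel).
#'
#' The non-negative problem is solved with Lawson-Hanson NNLS; when the
#' unconstrained-sum optimum exceeds one, the solution lies on the
#' sum-to-one boundary (convexity) and is re-solved with a sum-to-one
#' penalty row.
#'
#' @param beta probe-by-sample beta matrix containing the reference probes.
#' @param reference probe-by-cell-type matrix of reference methylation
#'   fractions; >= 2 cell types, full column rank on the shared probes.
#' @param sum_constraint "le_one" (default) or "eq_one".
#' @return sample-by-cell-type matrix of proportions.
#' @export
estimate_cell_proportions <- function(beta, reference,
                                      sum_constraint = c("le_one", "eq_one")) {
  sum_constraint <- match.arg(sum_constraint)
  if (ncol(reference) < 2)
    stop("reference must contain at least two cell types", call. = FALSE)
  if (any(reference < 0 | reference > 1))
    stop("reference betas must lie in [0, 1]", call. = FALSE)
  shared <- intersect(rownames(reference), rownames(beta))
  if (length(shared) < 2)
    stop("insufficient reference: fewer than 2 reference probes present in ",
         "the beta matrix", call. = FALSE)
  if (length(shared) < length(rownames(reference)))
    warning(nrow(reference) - length(shared),
            " reference probe(s) absent from the beta matrix; dropped")
  A <- reference[shared, , drop = FALSE]
  if (qr(A)$rank < ncol(A))
    stop("reference matrix is rank-deficient on the shared probes",
         call. = FALSE)
  props <- t(vapply(colnames(beta), function(s) {
    y <- beta[shared, s]
    ok <- !is.na(y)
    if (sum(ok) < 2)
      stop("insufficient reference: sample '", s,
           "' has fewer than 2 non-missing reference probes", call. = FALSE)
    solve_proportions(A[ok, , drop = FALSE], y[ok], sum_constraint)
  }, numeric(ncol(A))))
  dimnames(props) <- list(colnames(beta), colnames(reference))
  props
}

solve_proportions <- function(A, y, sum_constraint) {
  p <- pracma::lsqnonneg(A, y)$x
  if (sum_constraint == "eq_one" || sum(p) > 1 + 1e-9) {
    # project onto the sum-to-one face via a heavily weighted penalty row
    w <- 1e4 * max(1, sqrt(sum(A^2)))
    p <- pracma::lsqnonneg(rbind(A, rep(w, ncol(A))), c(y, w))$x
    p <- p / max(sum(p), .Machine$double.eps)  # exact renormalisation
  }
  p
}

#' Cell-composition-adjusted ("average cell") beta values
#'
#' Removes between-sample variation attributable to cell composition. Per
#' probe, a linear model of beta on the centred proportion columns is
#' fitted (ordinary least squares; optional ridge penalty `lambda` on the
#' composition coefficients); the adjusted value is the fit at the
#' cohort-mean composition plus the residual — the beta the probe would
#' show in a sample of average cellular make-up. Values falling outside
#' \[0, 1\] after adjustment are clipped and counted.
#'
#' With `lambda = 0` the adjustment is a projection, hence idempotent:
#' residuals are orthogonal to the centred proportions.
#'
#' @param beta probe-by-sample beta matrix (no missing values).
#' @param proportions sample-by-cell-type proportion matrix covering every
#'   sample in `beta`.
#' @param lambda ridge penalty on composition coefficients, default 0.
#' @return adjusted beta matrix with attribute `clipped` giving the number
#'   of values clipped into \[0, 1\].
#' @export
adjust_for_cells <- function(beta, proportions, lambda = 0) {
  missing_samp <- setdiff(colnames(beta), rownames(proportions))
  if (length(missing_samp))
    stop("samples absent from proportions: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  X <- proportions[colnames(beta), , drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  # hat matrix of the centred composition design; pseudo-inverse tolerates
  # the rank deficiency induced by sum-to-one compositions when lambda = 0
  s <- svd(Xc)
  keep <- s$d > max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
  if (lambda == 0) {
    U <- s$u[, keep, drop = FALSE]
    H <- U %*% t(U)
  } else {
    d <- s$d[keep]
    U <- s$u[, keep, drop = FALSE]
    H <- U %*% diag(d^2 / (d^2 + lambda), length(d)) %*% t(U)
  }
  adjusted <- beta - beta %*% H  # per probe: y - fitted composition effect
  clipped <- sum(adjusted < 0 | adjusted > 1)
  adjusted[adjusted < 0] <- 0
  adjusted[adjusted > 1] <- 1
  attr(adjusted, "clipped") <- clipped
  adjusted
}
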