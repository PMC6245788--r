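# Fixture builders and independent oracles shared across the suite.

# Tiny named beta matrix
tiny_beta <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  values
}

# Minimal twin sample sheet: n_disc discordant + n_conc concordant +
# n_heal healthy pairs, twin_a of discordant pairs affected.
tiny_sheet <- function(n_disc = 2, n_conc = 0, n_heal = 0) {
  mk <- function(prefix, n, statuses, class) {
    if (n == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(i) {
      pid <- sprintf("%s%02d", prefix, i)
      data.frame(sample_id = paste0(pid, c("a", "b")), pair_id = pid,
                 role = c("twin_a", "twin_b"), status = statuses,
                 pair_class = class, stringsAsFactors = FALSE)
    }))
  }
  validate_sample_sheet(rbind(
    mk("D", n_disc, c("affected", "healthy"), "discordant"),
    mk("C", n_conc, c("affected", "affected"), "concordant"),
    mk("H", n_heal, c("healthy", "healthy"), "healthy")))
}

# Independent oracle for the one-tailed F-test p-value: numerical
# integration of the F density over the upper tail.
f_upper_tail_oracle <- function(Fstat, df1, df2) {
  stats::integrate(function(x) stats::df(x, df1, df2), Fstat, Inf,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Brute-force Benjamini-Hochberg step-up: for each p, the minimum of
# m * p_(j) / j over all sorted positions j at or after its own.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pos <- which(ord == i)
    q[i] <- min(1, min(m * p[ord[pos:m]] / (pos:m)))
  }
  q
}

# Constrained grid-search oracle for 3-type deconvolution: exhaustive
# search over the simplex {p >= 0, sum p <= 1} at the given step.
grid_search_proportions <- function(A, y, step = 0.001) {
  stopifnot(ncol(A) == 3)
  p1 <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = p1, p2 = p1)
  grid <- grid[grid$p1 + grid$p2 <= 1, ]
  G <- crossprod(A)
  Ay <- crossprod(A, y)
  best <- NULL; best_val <- Inf
  # rss(p) = y'y - 2 p'A'y + p'Gp, minimised over p3 for each (p1, p2)
  for (p3 in p1) {
    P <- cbind(grid$p1, grid$p2, p3)
    ok <- grid$p1 + grid$p2 + p3 <= 1
    if (!any(ok)) next
    P <- P[ok, , drop = FALSE]
    val <- -2 * P %*% Ay + rowSums((P %*% G) * P)
    i <- which.min(val)
    if (val[i] < best_val) { best_val <- val[i]; best <- P[i, ] }
  }
  unname(best)
}

# Null-calibration cohort: independent measurement noise only (no pair
# effects, no composition, intermediate means away from the boundaries).
null_cohort_config <- function(seed, n_probes = 10000, noise_sd = 0.005) {
  twin_sim_config(n_probes = n_probes, pair_effect_sd = 0,
                  baseline_weights = c(0, 1, 0), noise_sd = noise_sd,
                  n_outlier_probes = 0, n_celltypes = 0,
                  detection_fail_rate = 0, seed = seed)
}

# Recovery cohort: 20 single-co-twin outliers of 0.3 on a baseline sd of
# 0.01 among 10,000 probes.
recovery_cohort_config <- function(seed) {
  twin_sim_config(n_probes = 10000, pair_effect_sd = 0, noise_sd = 0.01,
                  n_outlier_probes = 20, outlier_delta = 0.3,
                  n_celltypes = 0, detection_fail_rate = 0, seed = seed)
}
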