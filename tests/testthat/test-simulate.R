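test_that("cohorts are reproducible by seed and differ across seeds", {
  cfg1 <- twin_sim_config(n_probes = 200, seed = 1)
  coh_a <- generate_cohort(cfg1)
  coh_b <- generate_cohort(cfg1)
  expect_identical(coh_a$beta, coh_b$beta)
  expect_identical(coh_a$detp, coh_b$detp)
  expect_identical(coh_a$truth, coh_b$truth)
  coh_c <- generate_cohort(twin_sim_config(n_probes = 200, seed = 2))
  expect_false(identical(coh_a$beta, coh_c$beta))
})

test_that("the default design matches the twin-study structure", {
  coh <- generate_cohort(twin_sim_config(n_probes = 50, seed = 3))
  expect_identical(ncol(coh$beta), 34L)
  counts <- table(coh$sheet$pair_class[!duplicated(coh$sheet$pair_id)])
  expect_identical(as.integer(counts[c("discordant", "concordant", "healthy")]),
                   c(6L, 4L, 7L))
  expect_true(all(coh$beta >= 0 & coh$beta <= 1))
  expect_true(all(coh$detp >= 0 & coh$detp <= 1))
  expect_identical(dimnames(coh$detp), dimnames(coh$beta))
  expect_identical(nrow(coh$truth$outliers), 13L)
  # every injected carrier is an affected discordant co-twin
  aff <- discordant_samples(coh$sheet)$affected
  expect_true(all(coh$truth$outliers$carrier %in% aff))
})

test_that("zero noise and no outliers make co-twins identical, so F = 1 everywhere", {
  cfg <- twin_sim_config(n_probes = 100, noise_sd = 0, n_outlier_probes = 0,
                         n_celltypes = 0, detection_fail_rate = 0, seed = 4)
  coh <- generate_cohort(cfg)
  for (pid in unique(coh$sheet$pair_id)) {
    ids <- coh$sheet$sample_id[coh$sheet$pair_id == pid]
    expect_identical(coh$beta[, ids[1]], coh$beta[, ids[2]],
                     label = paste("pair", pid))
  }
  st <- scan_outliers(coh$beta, coh$sheet)
  pos <- st$F[!is.nan(st$F)]
  expect_true(all(abs(pos - 1) < 1e-9))
})

test_that("outlier sign points away from the nearer boundary and clips are counted", {
  cfg <- twin_sim_config(n_probes = 2000, n_outlier_probes = 50,
                         baseline_logit_sd = 1, seed = 5, n_celltypes = 0)
  coh <- generate_cohort(cfg)
  tr <- coh$truth$outliers
  carrier_vals <- coh$beta[cbind(tr$probe_id, tr$carrier)]
  expect_true(all(carrier_vals >= 0 & carrier_vals <= 1))
  expect_true(is.numeric(coh$truth$clipped) && coh$truth$clipped >= 0)
  # the shifted value stays well inside [0,1]: delta always realizable
  expect_true(all(abs(carrier_vals - 0.5) < 0.5))
})

test_that("invalid configurations are rejected", {
  expect_error(twin_sim_config(n_probes = 10, n_outlier_probes = 11),
               "more outlier probes")
  expect_error(twin_sim_config(n_probes = 10, n_outlier_probes = 0,
                               n_composition_probes = 11),
               "more composition probes")
  expect_error(twin_sim_config(n_discordant = 0, n_outlier_probes = 5),
               "discordant pair")
  expect_error(generate_cell_reference(K = 1), "at least two")
  expect_error(generate_cell_reference(K = 3, separation = 0.01),
               "separation too small")
})

test_that("generated references are full rank and support exact deconvolution", {
  ref <- generate_cell_reference(K = 6, n_reference_probes = 100, seed = 6)
  expect_identical(qr(ref)$rank, 6L)
  expect_true(all(ref >= 0 & ref <= 1))
  w <- c(0.25, 0.15, 0.1, 0.2, 0.05, 0.25)
  b <- tiny_beta(ref %*% w, probes = rownames(ref), samples = "mix")
  est <- estimate_cell_proportions(b, ref)
  expect_lt(max(abs(est[1, ] - w)), 1e-6)
})

test_that("written cohorts round-trip through the package readers", {
  cfg <- twin_sim_config(n_probes = 60, seed = 7)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  b <- read_beta_matrix(paths[["beta"]])
  expect_equal(b, coh$beta, tolerance = 1e-9)
  sheet <- read_sample_sheet(paths[["sheet"]])
  expect_identical(sheet$pair_class, coh$sheet$pair_class)
  detp <- read_detection_p(paths[["detp"]], beta = b)
  expect_identical(dim(detp), dim(coh$detp))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$outliers$probe_id, coh$truth$outliers$probe_id)
})

test_that("power is non-decreasing in the outlier magnitude", {
  power_at <- function(delta) {
    mean(vapply(1:3, function(s) {
      cfg <- twin_sim_config(n_probes = 2000, pair_effect_sd = 0,
                             noise_sd = 0.01, n_outlier_probes = 10,
                             outlier_delta = delta, n_celltypes = 0,
                             detection_fail_rate = 0, seed = 100 + s)
      coh <- generate_cohort(cfg)
      st <- scan_outliers(coh$beta, coh$sheet)
      mean(coh$truth$outliers$probe_id %in% st$probe_id[st$outlier])
    }, numeric(1)))
  }
  p <- vapply(c(0.1, 0.2, 0.3), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("with outliers disabled, discoveries at q <= 0.05 are essentially absent", {
  disc <- vapply(1:10, function(s) {
    coh <- generate_cohort(null_cohort_config(s, n_probes = 2000))
    st <- scan_outliers(coh$beta, coh$sheet)
    sum(st$q <= 0.05)
  }, numeric(1))
  expect_lte(mean(disc), 0.5)
})
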