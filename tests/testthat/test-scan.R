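scan_fixture <- function(seed = 51, n_probes = 400, n_out = 4,
                         noise_sd = 0.005, delta = 0.3) {
  cfg <- twin_sim_config(n_probes = n_probes, pair_effect_sd = 0,
                         noise_sd = noise_sd, n_outlier_probes = n_out,
                         outlier_delta = delta, n_celltypes = 0,
                         detection_fail_rate = 0, seed = seed)
  generate_cohort(cfg)
}

test_that("scan applies the two-stage rule: q cut then strict range cut", {
  coh <- scan_fixture()
  st <- scan_outliers(coh$beta, coh$sheet, q_threshold = 0.05,
                      range_threshold_pp = 10)
  expect_identical(nrow(st), 400L)
  expect_true(all(st$df1 == 5L & st$df2 == 5L))
  expect_true(all(st$p >= 0 & st$p <= 1 & st$q >= 0 & st$q <= 1))
  expect_identical(st$outlier, st$q <= 0.05 & st$range_diff_pp > 10)
  funnel <- attr(st, "funnel")
  expect_identical(funnel$tested, 400L)
  expect_identical(funnel$significant,
                   funnel$outliers + funnel$range_filtered)
  # a significant probe whose range difference sits at the threshold is
  # filtered, not flagged (strict inequality)
  i <- which.min(st$q)
  st2 <- scan_outliers(coh$beta, coh$sheet,
                       range_threshold_pp = st$range_diff_pp[i])
  expect_false(st2$outlier[i])
})

test_that("scan statistics match the single-probe F-test", {
  coh <- scan_fixture(seed = 52, n_probes = 50, n_out = 0)
  st <- scan_outliers(coh$beta, coh$sheet)
  grp <- discordant_samples(coh$sheet)
  for (i in c(1, 17, 50)) {
    single <- variance_f_test(coh$beta[i, grp$affected],
                              coh$beta[i, grp$healthy])
    expect_equal(st$F[i], single$F, tolerance = 1e-12)
    expect_equal(st$p[i], single$p, tolerance = 1e-12)
    expect_equal(st$affected_range_pct[i],
                 beta_range(coh$beta[i, grp$affected]), tolerance = 1e-12)
  }
})

test_that("the one-tailed scan never flags probes with the healthy group more variable", {
  coh <- scan_fixture(seed = 53, n_probes = 500, n_out = 5)
  st <- scan_outliers(coh$beta, coh$sheet)
  grp <- discordant_samples(coh$sheet)
  vx <- apply(coh$beta[, grp$affected], 1, var)
  vy <- apply(coh$beta[, grp$healthy], 1, var)
  expect_true(all(st$F[st$outlier] > 1))
  expect_true(all(vx[st$outlier] > vy[st$outlier]))
  expect_true(all(st$p[st$F < 1] > 0.5))
})

test_that("increasing one affected value's deviation never decreases F", {
  coh <- scan_fixture(seed = 54, n_probes = 20, n_out = 0)
  grp <- discordant_samples(coh$sheet)
  aff <- coh$beta[1, grp$affected]
  hea <- coh$beta[1, grp$healthy]
  shifts <- seq(0, 0.3, by = 0.02)
  Fs <- vapply(shifts, function(d) {
    a <- aff; a[3] <- a[3] + d
    variance_f_test(a, hea)$F
  }, numeric(1))
  expect_true(all(diff(Fs) >= -1e-12))
})

test_that("missing values at scan time are a contract error", {
  coh <- scan_fixture(seed = 55, n_probes = 30, n_out = 0)
  b <- coh$beta
  b[2, discordant_samples(coh$sheet)$all[1]] <- NA
  expect_error(scan_outliers(b, coh$sheet), "filter_complete")
})

test_that("the deviant affected co-twin is identified with its deviation", {
  sheet <- tiny_sheet(3)
  v <- c(D01a = 0.05, D01b = 0.06, D02a = 0.40, D02b = 0.05,
         D03a = 0.04, D03b = 0.06)
  res <- identify_outlier_cotwin(v, sheet)
  expect_identical(res$sample_id, "D02a")
  expect_identical(res$pair_id, "D02")
  expect_equal(res$deviation_pp, (0.40 - median(v)) * 100, tolerance = 1e-12)
  expect_false(res$tie)
  # exact tie: lexicographically first affected sample wins, tie flagged
  v2 <- c(D01a = 0.30, D01b = 0.10, D02a = 0.30, D02b = 0.10,
          D03a = 0.20, D03b = 0.20)
  res2 <- identify_outlier_cotwin(v2, sheet)
  expect_identical(res2$sample_id, "D01a")
  expect_true(res2$tie)
})

test_that("injected carriers are recovered exactly at low noise", {
  coh <- scan_fixture(seed = 56, n_probes = 500, n_out = 6, noise_sd = 0.01)
  st <- scan_outliers(coh$beta, coh$sheet)
  tr <- coh$truth$outliers
  flagged <- tr[tr$probe_id %in% st$probe_id[st$outlier], ]
  expect_gte(nrow(flagged), 5)
  for (i in seq_len(nrow(flagged))) {
    found <- identify_outlier_cotwin(coh$beta[flagged$probe_id[i], ],
                                     coh$sheet)
    expect_identical(found$sample_id, flagged$carrier[i])
    expect_gt(found$deviation_pp, 20)
  }
})
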