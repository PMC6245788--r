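#' Configuration for a synthetic monozygotic-twin methylation cohort
#'
#' Defaults emulate the structure of the twin study design the pipeline
#' targets: 6 discordant, 4 concordant and 7 healthy MZ pairs (34
#' samples); probe means drawn from a hypo/intermediate/hyper mixture;
#' within-pair deviations shared by both co-twins (MZ identity) on the
#' logit scale; per-sample measurement noise on the beta scale; optional
#' cell-composition confounding; and rare large single-co-twin outlier
#' deviations carried by one affected co-twin each.
#'
#' @param n_probes number of probes, default 10000 (a desk-scale stand-in
#'   for a ~450K array; any size works).
#' @param n_discordant,n_concordant,n_healthy pair counts, defaults 6/4/7.
#' @param baseline_centers,baseline_weights mixture of per-probe mean
#'   methylation levels, defaults centers (0.05, 0.50, 0.92) with weights
#'   (0.3, 0.4, 0.3).
#' @param baseline_logit_sd spread of probe means around their mixture
#'   centre, logit scale, default 0.5.
#' @param pair_effect_sd sd of the shared within-pair deviation, logit
#'   scale, default 0.03 (reproduces healthy-group beta ranges of ~1-2
#'   percentage points in groups of six co-twins).
#' @param noise_sd per-sample measurement noise sd, beta scale,
#'   default 0.005.
#' @param n_outlier_probes probes carrying an injected single-co-twin
#'   outlier, default 13.
#' @param outlier_delta beta-scale outlier magnitude, default 0.3; the
#'   sign points away from the nearer boundary so the shift is always
#'   realizable in \[0, 1\].
#' @param n_celltypes number of leukocyte types (0 disables composition
#'   modelling), default 6.
#' @param dirichlet_alpha Dirichlet concentration vector for per-sample
#'   compositions; default a blood-like mean (granulocyte-dominated)
#'   times concentration 30.
#' @param n_composition_probes ordinary probes whose beta is linearly
#'   confounded with composition, default 0.
#' @param composition_effect_sd sd of the composition effect sizes (beta
#'   per unit proportion deviation), default 0.1.
#' @param cell_reference optional probe-by-type reference matrix (e.g.
#'   from [generate_cell_reference()]); when supplied, its probes are
#'   appended to the cohort with betas mixed from the reference by each
#'   sample's composition, so reference-based deconvolution is exercised
#'   end to end.
#' @param detection_fail_rate fraction of (probe, sample) cells given a
#'   failing detection p-value, default 0.001.
#' @param seed integer seed; the cohort is fully reproducible given the
#'   configuration.
#' @return a `twin_sim_config` list.
#' @export
twin_sim_config <- function(n_probes = 10000,
                            n_discordant = 6, n_concordant = 4, n_healthy = 7,
                            baseline_centers = c(0.05, 0.50, 0.92),
                            baseline_weights = c(0.3, 0.4, 0.3),
                            baseline_logit_sd = 0.5,
                            pair_effect_sd = 0.03,
                            noise_sd = 0.005,
                            n_outlier_probes = 13,
                            outlier_delta = 0.3,
                            n_celltypes = 6,
                            dirichlet_alpha = NULL,
                            n_composition_probes = 0,
                            composition_effect_sd = 0.1,
                            cell_reference = NULL,
                            detection_fail_rate = 0.001,
                            seed = 1) {
  if (n_probes < 1 || n_discordant < 0 || n_concordant < 0 || n_healthy < 0)
    stop("counts must be non-negative (and n_probes >= 1)", call. = FALSE)
  if (n_outlier_probes > n_probes)
    stop("more outlier probes than probes", call. = FALSE)
  if (n_outlier_probes > 0 && n_discordant < 1)
    stop("outlier probes need at least one discordant pair", call. = FALSE)
  if (n_composition_probes > n_probes)
    stop("more composition probes than probes", call. = FALSE)
  if (is.null(dirichlet_alpha) && n_celltypes > 0) {
    dirichlet_alpha <- if (n_celltypes == 6)
      30 * c(0.06, 0.15, 0.10, 0.07, 0.07, 0.55)
    else rep(2, n_celltypes)
  }
  structure(list(
    n_probes = n_probes, n_discordant = n_discordant,
    n_concordant = n_concordant, n_healthy = n_healthy,
    baseline_centers = baseline_centers, baseline_weights = baseline_weights,
    baseline_logit_sd = baseline_logit_sd,
    pair_effect_sd = pair_effect_sd, noise_sd = noise_sd,
    n_outlier_probes = n_outlier_probes, outlier_delta = outlier_delta,
    n_celltypes = n_celltypes, dirichlet_alpha = dirichlet_alpha,
    n_composition_probes = n_composition_probes,
    composition_effect_sd = composition_effect_sd,
    cell_reference = cell_reference,
    detection_fail_rate = detection_fail_rate,
    seed = seed), class = "twin_sim_config")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic twin cohort with ground truth
#'
#' Simulates a probe-by-sample beta matrix under the model described in
#' [twin_sim_config()]: per-probe means from the baseline mixture, a
#' logit-scale deviation shared by both co-twins of each pair, optional
#' composition effects, beta-scale measurement noise, and a single
#' affected co-twin shifted by the outlier delta at each injected probe.
#' All betas are clipped to \[0, 1\] (clips counted in the truth).
#'
#' @param config a [twin_sim_config()].
#' @return list with `beta` (matrix), `sheet` (sample sheet), `detp`
#'   (detection p-values), `annotation` (all-autosomal probe annotation),
#'   `proportions` (true sample compositions, or NULL), and `truth`
#'   (injected outliers, composition probes, clip count, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  set.seed(config$seed)
  sheet <- make_sample_sheet(config)
  n_samp <- nrow(sheet)
  npr <- config$n_probes
  probe_ids <- sprintf("sim%06d", seq_len(npr))

  comp <- sample(seq_along(config$baseline_weights), npr, replace = TRUE,
                 prob = config$baseline_weights)
  mu_logit <- logit(config$baseline_centers)[comp] +
    stats::rnorm(npr, 0, config$baseline_logit_sd)

  # shared within-pair deviation: one draw per (probe, pair), copied to
  # both co-twins
  pair_ids <- unique(sheet$pair_id)
  pair_fx <- matrix(stats::rnorm(npr * length(pair_ids), 0, config$pair_effect_sd),
                    npr, length(pair_ids), dimnames = list(NULL, pair_ids))
  base <- inv_logit(mu_logit + pair_fx[, sheet$pair_id, drop = FALSE])
  dimnames(base) <- list(probe_ids, sheet$sample_id)

  proportions <- NULL
  comp_truth <- NULL
  if (config$n_celltypes > 0) {
    proportions <- rdirichlet(n_samp, config$dirichlet_alpha)
    rownames(proportions) <- sheet$sample_id
    colnames(proportions) <- paste0("type", seq_len(config$n_celltypes))
    if (config$n_composition_probes > 0) {
      cp <- sample.int(npr, config$n_composition_probes)
      ctype <- sample.int(config$n_celltypes, config$n_composition_probes,
                          replace = TRUE)
      ceff <- stats::rnorm(config$n_composition_probes, 0,
                           config$composition_effect_sd)
      centred <- scale(proportions, center = TRUE, scale = FALSE)
      base[cp, ] <- base[cp, ] + ceff * t(centred[, ctype, drop = FALSE])
      comp_truth <- data.frame(probe_id = probe_ids[cp],
                               cell_type = colnames(proportions)[ctype],
                               effect = ceff, stringsAsFactors = FALSE)
    }
  }

  beta <- base + matrix(stats::rnorm(npr * n_samp, 0, config$noise_sd),
                        npr, n_samp)

  outlier_truth <- NULL
  if (config$n_outlier_probes > 0) {
    affected <- discordant_samples(sheet)$affected
    op <- sample.int(npr, config$n_outlier_probes)
    carrier <- sample(affected, config$n_outlier_probes, replace = TRUE)
    sign_delta <- ifelse(inv_logit(mu_logit[op]) > 0.5, -1, 1)
    delta <- sign_delta * config$outlier_delta
    beta[cbind(op, match(carrier, colnames(beta)))] <-
      beta[cbind(op, match(carrier, colnames(beta)))] + delta
    outlier_truth <- data.frame(probe_id = probe_ids[op],
                                carrier = carrier, delta = delta,
                                stringsAsFactors = FALSE)
  }

  if (!is.null(config$cell_reference)) {
    ref <- config$cell_reference
    if (ncol(ref) != config$n_celltypes)
      stop("cell_reference column count differs from n_celltypes",
           call. = FALSE)
    mixed <- ref %*% t(proportions) +
      matrix(stats::rnorm(nrow(ref) * n_samp, 0, config$noise_sd),
             nrow(ref), n_samp)
    rownames(mixed) <- rownames(ref)
    beta <- rbind(beta, mixed)
    probe_ids <- rownames(beta)
  }

  clipped <- sum(beta < 0 | beta > 1)
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1

  detp <- matrix(stats::runif(length(beta), 0, 1e-6),
                 nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (config$detection_fail_rate > 0) {
    fail <- stats::runif(length(detp)) < config$detection_fail_rate
    detp[fail] <- stats::runif(sum(fail), 2e-4, 1e-2)
  }

  annotation <- data.frame(
    probe_id = rownames(beta),
    chromosome = as.character(sample.int(22, nrow(beta), replace = TRUE)),
    position = sample.int(2e8, nrow(beta), replace = TRUE),
    gene_name = "", gene_region = "", stringsAsFactors = FALSE)

  list(beta = beta_matrix(beta), sheet = sheet, detp = detp,
       annotation = annotation, proportions = proportions,
       truth = list(outliers = outlier_truth,
                    composition_probes = comp_truth,
                    clipped = clipped, seed = config$seed))
}

make_sample_sheet <- function(config) {
  rows <- list()
  add_pairs <- function(prefix, n, class) {
    lapply(seq_len(n), function(i) {
      pid <- sprintf("%s%02d", prefix, i)
      status <- switch(class,
                       discordant = c("affected", "healthy"),
                       concordant = c("affected", "affected"),
                       healthy = c("healthy", "healthy"))
      data.frame(sample_id = paste0(pid, c("a", "b")),
                 pair_id = pid, role = c("twin_a", "twin_b"),
                 status = status, pair_class = class,
                 sex = "unknown", stringsAsFactors = FALSE)
    })
  }
  rows <- c(add_pairs("D", config$n_discordant, "discordant"),
            add_pairs("C", config$n_concordant, "concordant"),
            add_pairs("H", config$n_healthy, "healthy"))
  validate_sample_sheet(do.call(rbind, rows))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cell-type methylation reference
#'
#' Builds a discriminating-probe reference for K leukocyte types: each
#' probe is hypermethylated (by `separation`) in exactly one type, cycled
#' over the types, on a probe-specific baseline, plus small jitter. The
#' construction guarantees pairwise column separation and full column
#' rank, which is verified before returning.
#'
#' @param K number of cell types, >= 2.
#' @param n_reference_probes number of discriminating probes, default 100.
#' @param separation methylation offset (beta scale) distinguishing the
#'   target type at each probe, default 0.5; values below 0.05 are
#'   rejected as too weak for identifiable deconvolution.
#' @param seed integer seed.
#' @return probe-by-type reference matrix with betas in \[0, 1\].
#' @export
generate_cell_reference <- function(K = 6, n_reference_probes = 100,
                                    separation = 0.5, seed = 1) {
  if (K < 2) stop("need at least two cell types", call. = FALSE)
  if (separation < 0.05)
    stop("separation too small for an identifiable reference", call. = FALSE)
  if (n_reference_probes < K)
    stop("need at least one discriminating probe per cell type", call. = FALSE)
  set.seed(seed)
  target <- rep_len(seq_len(K), n_reference_probes)
  lo <- stats::runif(n_reference_probes, 0.05,
                     max(0.06, 1 - separation - 0.05))
  ref <- matrix(lo, n_reference_probes, K) +
    matrix(stats::rnorm(n_reference_probes * K, 0, 0.01), n_reference_probes, K)
  ref[cbind(seq_len(n_reference_probes), target)] <-
    ref[cbind(seq_len(n_reference_probes), target)] + separation
  ref[ref < 0] <- 0
  ref[ref > 1] <- 1
  dimnames(ref) <- list(sprintf("ref%04d", seq_len(n_reference_probes)),
                        paste0("type", seq_len(K)))
  if (qr(ref)$rank < K)
    stop("generated reference is rank-deficient; increase separation",
         call. = FALSE)
  ref
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits exactly what the readers consume: beta TSV, detection-p TSV,
#' sample-sheet CSV, annotation CSV, and the ground truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             detp = file.path(dir, "detection_p.tsv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             annotation = file.path(dir, "annotation.csv"),
             truth = file.path(dir, "truth.json"))
  write_beta_matrix(cohort$beta, paths["beta"])
  write_beta_matrix(cohort$detp, paths["detp"], digits = 6)
  utils::write.csv(cohort$sheet, paths["sheet"], row.names = FALSE)
  utils::write.csv(cohort$annotation, paths["annotation"], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
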