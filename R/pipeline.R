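#' Assemble a pipeline configuration
#'
#' Collects input paths, stage toggles and thresholds for [run_pipeline()].
#' Defaults reproduce the reference analysis: detection filter at p >
#' 1e-4, autosomes only, completeness over discordant-pair individuals,
#' cell adjustment on when a reference is supplied, scan at q <= 0.05
#' with a 10 pp range filter, validation thresholds z = 3 and 5 pp.
#'
#' @param beta_path path to the beta TSV (probes x samples).
#' @param sheet_path path to the sample-sheet CSV.
#' @param annotation_path path to the annotation CSV.
#' @param detp_path optional detection-p TSV; NULL disables that stage.
#' @param cell_reference_path optional cell-reference CSV (probes x
#'   types); NULL disables adjustment.
#' @param out_dir output directory.
#' @param detection_threshold,q_threshold,range_threshold_pp,z_threshold,shared_diff_threshold_pp
#'   stage thresholds (see the stage functions for semantics).
#' @param lambda ridge penalty for [adjust_for_cells()], default 0.
#' @param adjust logical; run cell adjustment (requires a reference).
#' @param seed integer seed recorded in the manifest (the reference
#'   pipeline itself is deterministic; the seed covers any stochastic
#'   extension and the provenance record).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(beta_path, sheet_path, annotation_path,
                            detp_path = NULL, cell_reference_path = NULL,
                            out_dir = "pipeline_out",
                            detection_threshold = 1e-4,
                            q_threshold = 0.05, range_threshold_pp = 10,
                            z_threshold = 3, shared_diff_threshold_pp = 5,
                            lambda = 0,
                            adjust = !is.null(cell_reference_path),
                            seed = 1) {
  cfg <- list(beta_path = beta_path, sheet_path = sheet_path,
              annotation_path = annotation_path, detp_path = detp_path,
              cell_reference_path = cell_reference_path, out_dir = out_dir,
              detection_threshold = detection_threshold,
              q_threshold = q_threshold,
              range_threshold_pp = range_threshold_pp,
              z_threshold = z_threshold,
              shared_diff_threshold_pp = shared_diff_threshold_pp,
              lambda = lambda, adjust = adjust, seed = seed)
  for (f in c("beta_path", "sheet_path", "annotation_path")) {
    if (!file.exists(cfg[[f]]))
      stop("config error: ", f, " does not exist: ", cfg[[f]], call. = FALSE)
  }
  for (f in c("detp_path", "cell_reference_path")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config error: ", f, " does not exist: ", cfg[[f]], call. = FALSE)
  }
  if (adjust && is.null(cell_reference_path))
    stop("config error: adjustment requested without a cell reference",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full epigenetic-outlier pipeline
#'
#' Executes read -> filter -> (cell adjustment) -> variance scan ->
#' pair validation -> report. Artifacts written to `config$out_dir`:
#' `results.tsv` (per-probe statistics, annotated), `outliers.bed`,
#' `validation.tsv`, `pair_profiles.tsv` (tidy per-pair table for
#' profile plots), `filter_report.json`, and `manifest.json` (config,
#' seed, input checksums, funnel counts, stage timings). Identical
#' config, inputs and seed reproduce identical outputs. A failing stage
#' aborts with the stage name and moves partial outputs to a
#' `.quarantine` directory.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `stats`, `validation`, `profiles`,
#'   `filter_report`, `funnel`, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      qdir <- paste0(out, ".quarantine")
      unlink(qdir, recursive = TRUE)
      if (dir.exists(out)) file.rename(out, qdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- run_stage("read", {
    beta <- read_beta_matrix(config$beta_path)
    sheet <- read_sample_sheet(config$sheet_path)
    annotation <- read_annotation(config$annotation_path)
    detp <- if (!is.null(config$detp_path))
      read_detection_p(config$detp_path, beta = beta)
    reference <- if (!is.null(config$cell_reference_path))
      read_beta_matrix(config$cell_reference_path, delimiter = ",")
    list(beta = beta, sheet = sheet, annotation = annotation,
         detp = detp, reference = reference)
  })

  filtered <- run_stage("filter", {
    filter_probes(inputs$beta, inputs$sheet, inputs$annotation,
                  detp = inputs$detp,
                  detection_threshold = config$detection_threshold)
  })

  beta <- filtered$beta
  clipped <- 0L
  if (config$adjust) {
    beta <- run_stage("adjust", {
      # proportions come from the unfiltered matrix so reference probes
      # removed by the funnel still inform the deconvolution
      props <- estimate_cell_proportions(inputs$beta, inputs$reference)
      adjust_for_cells(filter_complete(beta), props, lambda = config$lambda)
    })
    clipped <- attr(beta, "clipped")
  } else {
    beta <- filter_complete(beta)  # scan needs complete rows everywhere
  }

  stats <- run_stage("scan", {
    scan_outliers(beta, inputs$sheet,
                  q_threshold = config$q_threshold,
                  range_threshold_pp = config$range_threshold_pp)
  })
  funnel <- attr(stats, "funnel")

  validation <- NULL
  profiles <- NULL
  candidates <- stats[stats$outlier, , drop = FALSE]
  has_validation_pairs <-
    any(inputs$sheet$pair_class %in% c("concordant", "healthy"))
  if (nrow(candidates) > 0 && has_validation_pairs) {
    vres <- run_stage("validate", {
      profiles <- profile_pairs(
        beta, inputs$sheet, candidates$probe_id,
        z_threshold = config$z_threshold,
        shared_diff_threshold_pp = config$shared_diff_threshold_pp)
      list(profiles = profiles,
           report = validate_candidates(candidates, profiles))
    })
    profiles <- vres$profiles
    validation <- vres$report
  }

  run_stage("report", {
    write_results(stats, inputs$annotation, file.path(out, "results.tsv"))
    write_bed(stats, inputs$annotation, file.path(out, "outliers.bed"))
    write_filter_report(filtered$report, file.path(out, "filter_report.json"))
    if (!is.null(validation))
      utils::write.table(validation, file.path(out, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(profiles))
      utils::write.table(profiles, file.path(out, "pair_profiles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(unlist(Filter(Negate(is.null),
      config[c("beta_path", "sheet_path", "annotation_path",
               "detp_path", "cell_reference_path")])))),
    filter_report = unclass(filtered$report),
    funnel = funnel,
    pi0 = attr(stats, "pi0"),
    adjusted = config$adjust,
    values_clipped_in_adjustment = clipped,
    n_validated = if (!is.null(validation)) sum(validation$validated),
    timings_sec = timings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(stats = stats, validation = validation,
                 profiles = profiles, filter_report = filtered$report,
                 funnel = funnel, manifest = manifest))
}
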