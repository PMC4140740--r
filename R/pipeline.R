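.fnv1a <- function(s) {
  # simple polynomial rolling hash over a prime < 2^30 (stays exact in
  # double arithmetic); used only as a config fingerprint
  bytes <- utf8ToInt(s)
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 898954793
  sprintf("%08x", h)
}

.config_hash <- function(config) {
  # fingerprint of the scientific parameters; where the results land is
  # not part of the study identity
  config <- config[setdiff(sort(names(config)), "output_dir")]
  .fnv1a(paste(deparse(config), collapse = "\n"))
}

.log_line <- function(logfile, stage, msg) {
  line <- sprintf("%s INFO [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}

.write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Build a study configuration
#'
#' A flat key-value configuration for the end-to-end study runners.
#' Exactly one of `manifest` (a CSV of pre-existing masks/volumes) or
#' `synthetic` (a parameter list for the generators) must be given. The
#' effective configuration, its hash and the seed are echoed into every
#' report so that runs are reproducible; reruns with an identical
#' configuration produce byte-identical reports (timestamps go to the run
#' log only).
#'
#' @param study_type "precision" or "accuracy"
#' @param output_dir where reports are written
#' @param manifest path to a manifest CSV (precision:
#'   subject_id, rater_id, repeat_id, mask_path; accuracy: specimen,
#'   mri_mask_path, ct_path)
#' @param synthetic list of generator parameters; for precision any of
#'   `n_subjects, size_scale_cv, th_mean, th_sd`, for accuracy any formal
#'   of [simulateAccuracySpecimens()] except seed
#' @param isotropic_target analysis spacing in mm (NULL = min input
#'   spacing)
#' @param ct_params a [CtSegmentationParams-class]
#' @param seed integer master seed
#' @param write_volumes also write thickness maps and overlap label
#'   volumes (heavier I/O; reports are always written)
#' @export
studyConfig <- function(study_type = c("precision", "accuracy"),
                        output_dir, manifest = NULL, synthetic = NULL,
                        isotropic_target = NULL, ct_params = ctParams(),
                        seed = 1L, write_volumes = FALSE) {
  study_type <- match.arg(study_type)
  if (is.null(manifest) == is.null(synthetic))
    stop("exactly one of 'manifest' or 'synthetic' must be provided")
  list(study_type = study_type, output_dir = output_dir,
       manifest = manifest, synthetic = synthetic,
       isotropic_target = isotropic_target,
       ct_params = list(sigma = ct_params@sigma,
                        support = ct_params@support,
                        atten_lo = ct_params@atten_lo,
                        atten_hi = ct_params@atten_hi,
                        keep_largest_component =
                          ct_params@keep_largest_component),
       seed = as.integer(seed), write_volumes = isTRUE(write_volumes))
}

.load_precision_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "rater_id", "mask_path")
  if (!all(need %in% names(man)))
    stop("invalid manifest: needs columns ", paste(need, collapse = ", "))
  masks <- list()
  for (i in seq_len(nrow(man))) {
    s <- as.character(man$subject_id[i]); r <- as.character(man$rater_id[i])
    masks[[s]][[r]] <- readVolume(man$mask_path[i], as = "mask")
  }
  masks
}

#' Run a precision (reproducibility) study end to end
#'
#' Generates (or loads) the subjects x raters mask collection, runs the
#' full [precisionStudy()], and writes `precision_report.json`,
#' `pairwise.csv`, `morphometry.csv`, the effective configuration and a
#' run log into the output directory. With `write_volumes = TRUE` it also
#' writes per-mask thickness maps and per-pair overlap label volumes.
#'
#' @param config a [studyConfig()] list with `study_type = "precision"`
#' @return the [precisionStudy()] result, invisibly extended with `paths`
#' @export
runPrecision <- function(config) {
  stopifnot(identical(config$study_type, "precision"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  .log_line(logfile, "config", paste("hash", .config_hash(config),
                                     "seed", config$seed))
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    pop_args <- list(
      n_subjects = syn$n_subjects %||% 14L,
      size_scale_cv = syn$size_scale_cv %||% 0.08,
      th_mean = syn$th_mean %||% 1.15,
      th_sd = syn$th_sd %||% 0.10,
      seed = config$seed)
    if (!is.null(syn$geometry)) pop_args$geometry <- syn$geometry
    pop <- do.call(populationSpec, pop_args)
    .log_line(logfile, "synthetic",
              sprintf("simulating %d subjects x %d raters",
                      pop@n_subjects, 3L))
    cohort <- simulatePopulation(pop)
    masks <- cohort$masks
  } else {
    masks <- .load_precision_manifest(config$manifest)
    cohort <- NULL
  }
  nrep <- length(masks[[1]])
  if (nrep < 2L) stop("m_repeats < 2: need at least two raters/repeats")
  .log_line(logfile, "morphometry",
            sprintf("%d masks", length(masks) * nrep))
  study <- precisionStudy(masks,
                          isotropic_target = config$isotropic_target)

  report <- list(
    study_type = "precision",
    seed = config$seed,
    config_hash = .config_hash(config),
    units = list(cg_v = "mm^3", cg_s = "mm^2", cg_th = "mm",
                 spacing = "mm"),
    n_subjects = length(masks), n_raters = nrep,
    metrics = lapply(study$reports, function(r)
      list(mean = r@mean, pe_sd = r@pe_sd, pe_pct_cv = r@pe_pct_cv,
           dof = r@dof, dof_ok = r@dof_ok, icc = r@icc)),
    pairwise_r_mean = study$pairwise_r_mean,
    pairwise_r_sd = study$pairwise_r_sd)
  paths <- list(report = file.path(out, "precision_report.json"),
                pairwise = file.path(out, "pairwise.csv"),
                morphometry = file.path(out, "morphometry.csv"),
                config = file.path(out, "config.json"))
  .write_report_json(report, paths$report)
  write.csv(study$pairwise, paths$pairwise, row.names = FALSE)
  write.csv(study$morphometry, paths$morphometry, row.names = FALSE)
  .write_report_json(config, paths$config)
  if (isTRUE(config$write_volumes)) {
    for (s in names(masks)) {
      for (r in names(masks[[s]])) {
        tm <- thicknessMap(masks[[s]][[r]],
                           isotropic_target = config$isotropic_target)
        writeThicknessMap(tm, file.path(out,
                                        sprintf("thmap_%s_%s.nii.gz", s, r)))
      }
      prs <- utils::combn(names(masks[[s]]), 2, simplify = FALSE)
      for (p in prs) {
        om <- overlapMap(masks[[s]][[p[1]]], masks[[s]][[p[2]]])
        writeVolume(om$labels,
                    file.path(out, sprintf("overlap_%s_%s_%s.nii.gz",
                                           s, p[1], p[2])))
      }
    }
  }
  .log_line(logfile, "done", paths$report)
  study$paths <- paths
  study$truth <- if (!is.null(cohort)) cohort$truth else NULL
  invisible(study)
}

.load_accuracy_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "mri_mask_path", "ct_path")
  if (!all(need %in% names(man)))
    stop("invalid manifest: needs columns ", paste(need, collapse = ", "))
  specimens <- list()
  for (i in seq_len(nrow(man))) {
    specimens[[as.character(man$specimen[i])]] <- list(
      mri_mask = readVolume(man$mri_mask_path[i], as = "mask"),
      ct = readVolume(man$ct_path[i], as = "grayscale"))
  }
  specimens
}

#' Run a two-chain accuracy study end to end
#'
#' Generates (or loads) per-specimen MRI-chain masks and CT-chain volumes,
#' runs [accuracyStudy()] (the CT chain through [segmentCT()]), and writes
#' `accuracy_report.json` plus a scatter-data CSV.
#'
#' @param config a [studyConfig()] list with `study_type = "accuracy"`
#' @return the [accuracyStudy()] result, invisibly extended with `paths`
#' @export
runAccuracy <- function(config) {
  stopifnot(identical(config$study_type, "accuracy"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  .log_line(logfile, "config", paste("hash", .config_hash(config),
                                     "seed", config$seed))
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    args <- syn[intersect(names(syn),
                          setdiff(names(formals(simulateAccuracySpecimens)),
                                  "seed"))]
    args$seed <- config$seed
    specimens <- do.call(simulateAccuracySpecimens, args)
  } else {
    specimens <- .load_accuracy_manifest(config$manifest)
  }
  cp <- config$ct_params
  params <- ctParams(cp$sigma, cp$support, cp$atten_lo, cp$atten_hi,
                     cp$keep_largest_component)
  .log_line(logfile, "accuracy", sprintf("%d specimens", length(specimens)))
  study <- accuracyStudy(specimens, ct_params = params,
                         isotropic_target = config$isotropic_target)
  report <- list(
    study_type = "accuracy",
    seed = config$seed,
    config_hash = .config_hash(config),
    units = list(cg_v = "mm^3", cg_s = "mm^2", cg_th = "mm",
                 attenuation = "1/cm"),
    n_specimens = length(specimens),
    correlations = study$correlations,
    thickness_band = list(
      voxel_ref_mm = 0.45,
      fraction_within = study$thickness_band$fraction_within,
      differences = study$thickness_band$differences))
  paths <- list(report = file.path(out, "accuracy_report.json"),
                scatter = file.path(out, "scatter.csv"),
                config = file.path(out, "config.json"))
  .write_report_json(report, paths$report)
  write.csv(study$pairs, paths$scatter, row.names = FALSE)
  .write_report_json(config, paths$config)
  .log_line(logfile, "done", paths$report)
  study$paths <- paths
  invisible(study)
}
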