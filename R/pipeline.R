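# One-call orchestration: phantom (or volume directory) -> registration ->
# kinematics -> displacement -> noise floor -> reports.

#' Build a run configuration
#'
#' @param phantom a [PhantomSpec-class] (phantom mode), or NULL when
#'   reading volumes from disk.
#' @param volumeDir directory of TIFF phase stacks (used when `phantom` is
#'   NULL; see [readPhaseSeries()]).
#' @param subVolumes list of [SubVolumeSpec-class] or a path to a
#'   sub-volume CSV table.
#' @param rois named list of [ROIPointSet-class] or a path to an ROI CSV
#'   table.
#' @param regParams a [RegistrationParams-class].
#' @param policy an [OutlierPolicy-class].
#' @param scope outlier scope, "per_phase" or "whole_sv".
#' @param staticLabel optional label of an ossicle entry that is actually a
#'   static reference region; its motion feeds the noise-floor report.
#' @param noiseFloorBounds named bounds passed to [noiseFloor()].
#' @param amplification display amplification factor recorded with the
#'   outputs (default 100).
#' @param outDir optional output directory; when set, all results are
#'   written there.
#' @param seed integer seed controlling phantom noise.
#' @return A validated run-configuration list of class "ossimotionConfig".
#' @export
runConfig <- function(phantom = NULL, volumeDir = NULL, subVolumes,
                      rois = list(), regParams = registrationParams(),
                      policy = outlierPolicy(), scope = "per_phase",
                      staticLabel = NULL,
                      noiseFloorBounds = c(translation_um = 0.2,
                                           angle_deg = 0.002,
                                           displacement_um = 0.3),
                      amplification = 100, outDir = NULL, seed = 1L) {
  if (is.null(phantom) && is.null(volumeDir))
    stop("either a phantom spec or a volume directory is required")
  if (!is.null(phantom)) stopifnot(is(phantom, "PhantomSpec"))
  if (is.character(subVolumes)) {
    if (!file.exists(subVolumes)) stop("sub-volume table not found: ", subVolumes)
    subVolumes <- readSubVolumeTable(subVolumes)
  }
  if (is.character(rois)) {
    if (!file.exists(rois)) stop("ROI table not found: ", rois)
    vx <- if (!is.null(phantom)) phantom@voxelSize else 2.75
    rois <- readROITable(rois, voxelSize = vx)
  }
  if (!length(subVolumes)) stop("at least one sub-volume is required")
  if (!is.null(volumeDir) && is.null(phantom) &&
      !file.exists(file.path(volumeDir, "series.json")))
    stop("volume directory has no series.json: ", volumeDir)
  structure(list(phantom = phantom, volumeDir = volumeDir,
                 subVolumes = subVolumes, rois = rois, regParams = regParams,
                 policy = policy, scope = scope, staticLabel = staticLabel,
                 noiseFloorBounds = noiseFloorBounds,
                 amplification = amplification, outDir = outDir,
                 seed = as.integer(seed)),
            class = "ossimotionConfig")
}

#' Run the full motion-extraction pipeline
#'
#' Generates (or loads) the phase volumes, registers every sub-volume of
#' every ossicle against phase p0, averages the vetted transforms into
#' per-ossicle motion, tracks the ROIs and fits the constrained sine, and
#' derives the noise floor from the static reference region when one is
#' configured. A failure confined to one ossicle is recorded in the run log
#' and does not abort the others. Deterministic for a fixed seed.
#'
#' @param config a configuration from [runConfig()].
#' @return A list with elements `series` truth (phantom mode), `transforms`,
#'   `motions`, `traces`, `fits`, `noiseFloor`, `errors` and `log`.
#' @export
runMotionExtraction <- function(config) {
  stopifnot(inherits(config, "ossimotionConfig"))
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    ph@seed <- config$seed
    gen <- generatePhaseVolumes(ph)
    series <- gen$series
    truth <- gen$truth
  } else {
    series <- readPhaseSeries(config$volumeDir)
    truth <- NULL
  }
  n <- nPhases(series)
  labels <- vapply(config$subVolumes, function(s) s@label, character(1))
  errors <- list()
  transforms <- list()
  motions <- list()
  for (oss in unique(labels)) {
    res <- tryCatch({
      svs <- config$subVolumes[labels == oss]
      tr <- registerPhaseSeries(series, svs, config$regParams)
      mot <- ossicleMotion(tr, label = oss, voxelSize = voxelSize(series),
                           policy = config$policy, scope = config$scope,
                           phaseTimes = phaseTimes(series))
      list(tr = tr, mot = mot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[oss]] <- conditionMessage(res)
    } else {
      transforms[[oss]] <- res$tr
      motions[[oss]] <- res$mot
    }
  }

  nf <- NULL
  if (!is.null(config$staticLabel) &&
      !is.null(motions[[config$staticLabel]])) {
    roiStatic <- Filter(function(r) r@ossicle == config$staticLabel,
                        config$rois)
    if (length(roiStatic))
      nf <- noiseFloor(motions[[config$staticLabel]], roiStatic[[1L]],
                       config$noiseFloorBounds)
  }

  traces <- list()
  fits <- list()
  for (roi in config$rois) {
    if (!is.null(config$staticLabel) && roi@ossicle == config$staticLabel)
      next
    if (is.null(motions[[roi@ossicle]])) next
    trc <- displacePoints(motions[[roi@ossicle]], roi)
    fit <- fitSine(trc, f = series@fStim)
    unreliable <- !is.null(nf) && fit@A < nf@maxDisplacement
    traces[[roi@label]] <- trc
    fits[[roi@label]] <- list(fit = fit, A_um = fit@A, two_A_um = 2 * fit@A,
                              phi_cycles = fit@phi, f_hz = fit@f,
                              R2 = fit@R2, below_noise_floor = unreliable)
  }

  log <- list(n_phases = n, voxel_size_um = voxelSize(series),
              seed = config$seed, scope = config$scope,
              amplification = config$amplification,
              ossicles = names(motions), errors = errors,
              convergence = lapply(transforms, function(svl)
                vapply(svl, function(phl)
                  all(vapply(phl, function(tr) tr@converged, logical(1))),
                  logical(1))))

  out <- list(series = series, truth = truth, transforms = transforms,
              motions = motions, traces = traces, fits = fits,
              noiseFloor = nf, errors = errors, log = log)
  if (!is.null(config$outDir)) .writeRunOutputs(out, config)
  out
}

.writeRunOutputs <- function(out, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  writeTransforms(out$transforms, file.path(config$outDir, "transforms.json"))
  for (oss in names(out$motions))
    utils::write.csv(motionTable(out$motions[[oss]]),
                     file.path(config$outDir,
                               sprintf("motion_%s.csv", oss)),
                     row.names = FALSE)
  for (lab in names(out$traces))
    writeTraceCSV(out$traces[[lab]],
                  file.path(config$outDir, sprintf("trace_%s.csv", lab)))
  fitRecs <- lapply(out$fits, function(f)
    f[c("A_um", "two_A_um", "phi_cycles", "f_hz", "R2",
        "below_noise_floor")])
  jsonlite::write_json(fitRecs, file.path(config$outDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(out$noiseFloor)) {
    nf <- out$noiseFloor
    jsonlite::write_json(list(max_translation_um = nf@maxTranslation,
                              max_angle_deg = nf@maxAngle,
                              max_displacement_um = nf@maxDisplacement,
                              bounds = as.list(nf@bounds), pass = nf@pass,
                              failed = nf@failed),
                         file.path(config$outDir, "noise_floor.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$log, file.path(config$outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$outDir)
}
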