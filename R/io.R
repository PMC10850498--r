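# Readers and writers for the pipeline's on-disk formats: TIFF slice
# stacks per phase, timing CSV, gating YAML, coordinate tables CSV, and
# transform / motion JSON.

#' Write a phase series as TIFF slice stacks
#'
#' One directory per phase (`phase_00`, `phase_01`, ...), one 32-bit TIFF
#' per z slice, plus a `series.json` sidecar carrying the voxel size, phase
#' times and the intensity scale used to map grayscale values into the TIFF
#' range.
#'
#' @param series a [PhaseSeries-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhaseSeries <- function(series, dir) {
  stopifnot(is(series, "PhaseSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(vapply(series@volumes, range, numeric(2)))
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  for (j in seq_len(nPhases(series))) {
    pd <- file.path(dir, sprintf("phase_%02d", j - 1L))
    dir.create(pd, showWarnings = FALSE)
    v <- (series[[j]] - rng[1]) / diff(rng)
    for (k in seq_len(dim(v)[3]))
      tiff::writeTIFF(v[, , k], file.path(pd, sprintf("slice_%04d.tif", k - 1L)),
                      bits.per.sample = 32L)
  }
  meta <- list(n_phases = nPhases(series), voxel_size_um = voxelSize(series),
               f_stim_hz = series@fStim, phase_times_ms = series@phaseTimes,
               intensity_min = rng[1], intensity_max = rng[2])
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phase series written by [writePhaseSeries()]
#'
#' @param dir directory containing `phase_XX` subdirectories and
#'   `series.json`.
#' @return A [PhaseSeries-class].
#' @export
readPhaseSeries <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  vols <- lapply(seq_len(meta$n_phases) - 1L, function(j) {
    pd <- file.path(dir, sprintf("phase_%02d", j))
    files <- sort(list.files(pd, pattern = "^slice_\\d+\\.tif$",
                             full.names = TRUE))
    if (!length(files)) stop("no slices found in ", pd)
    slices <- lapply(files, tiff::readTIFF)
    v <- array(unlist(slices), c(dim(slices[[1L]]), length(slices)))
    v * (meta$intensity_max - meta$intensity_min) + meta$intensity_min
  })
  phaseSeries(vols, voxelSize = meta$voxel_size_um, fStim = meta$f_stim_hz,
              phaseTimes = meta$phase_times_ms)
}

#' Write / read frame timing as CSV (frame_index, timestamp_ms)
#'
#' @param clock a [FrameClock-class].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [FrameClock-class] (reader, with
#'   the exposure period inferred from the median timestamp increment).
#' @export
writeTiming <- function(clock, path) {
  stopifnot(is(clock, "FrameClock"))
  utils::write.csv(data.frame(frame_index = seq_along(clock@timestamps) - 1L,
                              timestamp_ms = clock@timestamps),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTiming
#' @param exposureTime effective exposure (ms) to attach on read; defaults
#'   to the inferred exposure period.
#' @export
readTiming <- function(path, exposureTime = NULL) {
  d <- utils::read.csv(path)
  per <- stats::median(diff(d$timestamp_ms))
  if (is.null(exposureTime)) exposureTime <- per
  frameClock(d$timestamp_ms[order(d$frame_index)], per, exposureTime)
}

#' Write / read a gating-signal description as YAML
#'
#' @param gating a [GatingSignal-class].
#' @param path YAML path with fields `f_stim_hz`, `t_ref_ms`.
#' @return `path` invisibly (writer); a [GatingSignal-class] (reader).
#' @export
writeGating <- function(gating, path) {
  stopifnot(is(gating, "GatingSignal"))
  yaml::write_yaml(list(f_stim_hz = gating@fStim, t_ref_ms = gating@tRef),
                   path)
  invisible(path)
}

#' @rdname writeGating
#' @export
readGating <- function(path) {
  y <- yaml::read_yaml(path)
  gatingSignal(y$f_stim_hz, y$t_ref_ms)
}

#' Read a sub-volume table
#'
#' CSV columns: `ossicle_label, cx, cy, cz, hx, hy, hz` (0-based voxel
#' units).
#'
#' @param path CSV path.
#' @return List of [SubVolumeSpec-class].
#' @export
readSubVolumeTable <- function(path) {
  d <- utils::read.csv(path)
  lapply(seq_len(nrow(d)), function(i)
    subVolumeSpec(d$ossicle_label[i], c(d$cx[i], d$cy[i], d$cz[i]),
                  c(d$hx[i], d$hy[i], d$hz[i])))
}

#' Read an ROI point table
#'
#' CSV columns: `roi_label, ossicle_label, x, y, z` (0-based voxel units);
#' rows sharing a label form one point set.
#'
#' @param path CSV path.
#' @param voxelSize um per voxel to attach.
#' @return Named list of [ROIPointSet-class].
#' @export
readROITable <- function(path, voxelSize = 2.75) {
  d <- utils::read.csv(path)
  labs <- unique(d$roi_label)
  out <- lapply(labs, function(l) {
    s <- d[d$roi_label == l, ]
    roiPointSet(l, s$ossicle_label[1L], as.matrix(s[, c("x", "y", "z")]),
                voxelSize = voxelSize)
  })
  stats::setNames(out, labs)
}

.transformRecord <- function(tr, ossicle = NA, sv = NA) {
  list(ossicle = ossicle, sv = sv, phase = tr@phase,
       R = as.numeric(t(tr@rotation)),     # row-major
       t = tr@translation, origin = tr@origin,
       converged = tr@converged, metric_value = tr@metricValue)
}

.recordTransform <- function(rec) {
  rigidTransform(matrix(unlist(rec$R), 3, 3, byrow = TRUE),
                 unlist(rec$t), unlist(rec$origin),
                 phase = if (is.null(rec$phase) || is.na(rec$phase))
                   NA_integer_ else as.integer(rec$phase),
                 converged = isTRUE(rec$converged),
                 metricValue = if (is.null(rec$metric_value)) NA_real_
                   else as.numeric(rec$metric_value))
}

#' Write / read per-(ossicle, sub-volume, phase) transforms as JSON
#'
#' Records carry the rotation matrix row-major, the translation, the
#' rotation-centre origin, and the convergence report.
#'
#' @param transforms named list (one entry per ossicle) of lists over
#'   sub-volumes of lists over phases of [RigidTransform-class].
#' @param path JSON path.
#' @return `path` invisibly (writer); the nested transform list (reader).
#' @export
writeTransforms <- function(transforms, path) {
  recs <- list()
  for (oss in names(transforms))
    for (s in seq_along(transforms[[oss]]))
      for (tr in transforms[[oss]][[s]])
        recs[[length(recs) + 1L]] <- .transformRecord(tr, oss, s - 1L)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransforms
#' @export
readTransforms <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- list()
  for (rec in recs) {
    oss <- rec$ossicle
    s <- rec$sv + 1L
    if (is.null(out[[oss]])) out[[oss]] <- list()
    if (length(out[[oss]]) < s) out[[oss]][[s]] <- list()
    tr <- .recordTransform(rec)
    out[[oss]][[s]][[tr@phase + 1L]] <- tr
  }
  out
}

#' Write / read a phase assignment as CSV (frame_index, phase)
#'
#' @param assignment a [PhaseAssignment-class].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [PhaseAssignment-class] (reader).
#' @export
writeAssignment <- function(assignment, path) {
  stopifnot(is(assignment, "PhaseAssignment"))
  utils::write.csv(data.frame(frame_index = seq_along(assignment@phase) - 1L,
                              phase = assignment@phase),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssignment
#' @param nPhases bin count to attach on read (defaults to max(phase) + 1).
#' @export
readAssignment <- function(path, nPhases = NULL) {
  d <- utils::read.csv(path)
  d <- d[order(d$frame_index), ]
  if (is.null(nPhases)) nPhases <- max(d$phase) + 1L
  new("PhaseAssignment", phase = as.integer(d$phase),
      nPhases = as.integer(nPhases))
}

#' Write bin statistics as a JSON report
#'
#' @param stats the list returned by [binStatistics()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeBinStatistics <- function(stats, path) {
  jsonlite::write_json(stats[setdiff(names(stats), "frames")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a profile matrix as CSV (position column + one column per phase)
#'
#' @param pm a [ProfileMatrix-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeProfileMatrix <- function(pm, path) {
  stopifnot(is(pm, "ProfileMatrix"))
  d <- data.frame(position_vox = pm@positions, pm@matrix)
  names(d)[-1] <- sprintf("phase_%02d", seq_len(ncol(pm@matrix)) - 1L)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a standard-deviation projection as a TIFF image
#'
#' @param img 2D matrix from [stdProjection()].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
writeStdProjection <- function(img, path) {
  mx <- max(img)
  tiff::writeTIFF(if (mx > 0) img / mx else img, path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Write a displacement trace as CSV
#'
#' Columns: phase, t_ms, dx_um, dy_um, dz_um, D_signed_um, sd_um.
#'
#' @param trace a [DisplacementTrace-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "DisplacementTrace"))
  d <- data.frame(phase = seq_along(trace@times) - 1L, t_ms = trace@times,
                  dx_um = trace@meanDisplacement[, 1],
                  dy_um = trace@meanDisplacement[, 2],
                  dz_um = trace@meanDisplacement[, 3],
                  D_signed_um = trace@signedNorm, sd_um = trace@sd)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
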