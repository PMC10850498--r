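#' @useDynLib ossimotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @include AllGenerics.R
NULL

.unit_tol <- 1e-9

# ---------------------------------------------------------------------------
# Rigid transforms and rotations
# ---------------------------------------------------------------------------

#' Rigid (Euclidean) transform of one body between two motion phases
#'
#' Describes the motion of a rigid body from the reference phase p0 to phase
#' pj as a rotation about a stated centre followed by a translation: an
#' absolute point x at p0 maps to `R %*% (x - origin) + origin + t` at pj.
#' All lengths are in voxel units; `origin` is in absolute 0-based voxel
#' coordinates.
#'
#' @slot rotation 3x3 rotation matrix (orthonormal, det +1).
#' @slot translation numeric 3-vector, voxels.
#' @slot origin numeric 3-vector: the rotation centre the transform is
#'   expressed from.
#' @slot phase integer phase index j (NA if not tied to a phase).
#' @slot converged logical: did the producing optimisation converge.
#' @slot metricValue numeric: final similarity-metric value (NA if exact).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 origin = "numeric", phase = "integer",
                 converged = "logical", metricValue = "numeric"),
  prototype(phase = NA_integer_, converged = TRUE, metricValue = NA_real_))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation matrix is not orthonormal (R'R != I within 1e-6)")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have det +1 within 1e-6")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (length(object@origin) != 3L) return("origin must be length 3")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector (voxels).
#' @param origin rotation centre, absolute 0-based voxel coordinates.
#' @param phase optional integer phase index.
#' @param converged,metricValue optional provenance of an estimated transform.
#' @return A [RigidTransform-class] object.
#' @examples
#' rigidTransform(diag(3), c(1, 0, 0), origin = c(32, 32, 32))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           origin = c(0, 0, 0), phase = NA_integer_,
                           converged = TRUE, metricValue = NA_real_) {
  new("RigidTransform", rotation = unname(as.matrix(rotation)),
      translation = as.numeric(translation), origin = as.numeric(origin),
      phase = as.integer(phase), converged = converged,
      metricValue = as.numeric(metricValue))
}

#' @rdname rotationMatrix
#' @export
setMethod("rotationMatrix", "RigidTransform", function(x) x@rotation)

#' @rdname translationVector
#' @export
setMethod("translationVector", "RigidTransform", function(x) x@translation)

#' @rdname transformOrigin
#' @export
setMethod("transformOrigin", "RigidTransform", function(x) x@origin)

setMethod("show", "RigidTransform", function(object) {
  aa <- toAxisAngle(object@rotation)
  cat("RigidTransform (origin ", paste(signif(object@origin, 6), collapse = ", "),
      ")\n", sep = "")
  cat("  angle: ", signif(aa@angle, 6), " deg about axis (",
      paste(signif(aa@axis, 4), collapse = ", "), ")\n", sep = "")
  cat("  translation (voxels): ",
      paste(signif(object@translation, 6), collapse = ", "), "\n", sep = "")
  if (!is.na(object@phase)) cat("  phase:", object@phase, "\n")
})

#' Axis-angle representation of a rotation
#'
#' @slot axis unit 3-vector (convention (0,0,1) when degenerate).
#' @slot angle rotation magnitude in degrees, in [0, 180].
#' @slot degenerate logical: angle below the numeric threshold (1e-6 deg),
#'   in which case the axis is not identifiable.
#' @export
setClass("AxisAngle",
  representation(axis = "numeric", angle = "numeric", degenerate = "logical"))

setValidity("AxisAngle", function(object) {
  if (length(object@axis) != 3L) return("axis must be length 3")
  if (!object@degenerate && abs(sqrt(sum(object@axis^2)) - 1) > .unit_tol)
    return("axis must be unit norm within 1e-9")
  if (object@angle < 0 || object@angle > 180)
    return("angle must lie in [0, 180] degrees")
  TRUE
})

setMethod("show", "AxisAngle", function(object) {
  cat("AxisAngle: ", signif(object@angle, 6), " deg about (",
      paste(signif(object@axis, 4), collapse = ", "), ")",
      if (object@degenerate) "  [degenerate]", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Phase-volume series
# ---------------------------------------------------------------------------

#' Ordered series of 3D volumes, one per motion phase
#'
#' The pipeline's central image container: `n` co-registered grayscale
#' volumes sharing one grid, one per time window ("phase") of the periodic
#' motion cycle.
#'
#' @slot volumes list of 3D numeric arrays with identical dimensions,
#'   indexed (x, y, z).
#' @slot voxelSize physical voxel edge length, micrometres.
#' @slot phaseTimes numeric vector (ms): the within-cycle time each phase
#'   volume represents.
#' @slot fStim stimulation frequency (Hz) whose period the phases subdivide.
#' @export
setClass("PhaseSeries",
  representation(volumes = "list", voxelSize = "numeric",
                 phaseTimes = "numeric", fStim = "numeric"))

setValidity("PhaseSeries", function(object) {
  if (length(object@volumes) < 1L) return("need at least one volume")
  d <- dim(object@volumes[[1L]])
  if (length(d) != 3L) return("volumes must be 3D arrays")
  for (v in object@volumes)
    if (!identical(dim(v), d)) return("all volumes must share one grid")
  if (length(object@phaseTimes) != length(object@volumes))
    return("phaseTimes must have one entry per volume")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' Construct a PhaseSeries
#'
#' @param volumes list of 3D arrays (common dimensions), one per phase.
#' @param voxelSize voxel edge length in um (default 2.75).
#' @param fStim stimulation frequency in Hz (default 128).
#' @param phaseTimes per-phase times in ms; default `j/n` of the stimulation
#'   period for phases j = 0..n-1.
#' @return A [PhaseSeries-class].
#' @export
phaseSeries <- function(volumes, voxelSize = 2.75, fStim = 128,
                        phaseTimes = NULL) {
  n <- length(volumes)
  if (is.null(phaseTimes))
    phaseTimes <- (seq_len(n) - 1L) / n * 1000 / fStim
  new("PhaseSeries", volumes = volumes, voxelSize = voxelSize,
      phaseTimes = phaseTimes, fStim = fStim)
}

#' @rdname nPhases
#' @export
setMethod("nPhases", "PhaseSeries", function(x) length(x@volumes))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PhaseSeries", function(x) x@voxelSize)

#' @rdname phaseTimes
#' @export
setMethod("phaseTimes", "PhaseSeries", function(x) x@phaseTimes)

#' Extract one phase volume
#'
#' @param x a [PhaseSeries-class].
#' @param i phase index, 1-based as usual for R lists (phase p0 is `x[[1]]`).
#' @return 3D numeric array.
#' @export
setMethod("[[", "PhaseSeries", function(x, i) x@volumes[[i]])

setMethod("show", "PhaseSeries", function(object) {
  d <- dim(object@volumes[[1L]])
  cat("PhaseSeries:", length(object@volumes), "phases,",
      paste(d, collapse = " x "), "voxels,",
      object@voxelSize, "um/voxel, f =", object@fStim, "Hz\n")
})

# ---------------------------------------------------------------------------
# Phantom specification
# ---------------------------------------------------------------------------

#' Specification of one rigid body in a synthetic phantom
#'
#' Each body is a textured solid that moves sinusoidally as a rigid body:
#' at within-cycle time fraction u, the body is rotated by
#' `angleAmplitude * sin(2*pi*(u + phaseOffset))` degrees about `motionAxis`
#' through its centre, and translated by
#' `translationAmplitude * sin(2*pi*(u + phaseOffset))` voxels.
#'
#' @slot label short body name.
#' @slot shape one of "ellipsoid", "capsule", "L-prism", "arch".
#' @slot center absolute 0-based voxel coordinates of the body centre.
#' @slot size numeric 3-vector of half-extents, voxels.
#' @slot textureSeed integer seed freezing the body's internal texture.
#' @slot motionAxis unit 3-vector.
#' @slot angleAmplitude peak rotation angle, degrees.
#' @slot translationAmplitude numeric 3-vector of peak translation, voxels.
#' @slot phaseOffset fraction of cycle in [0, 1).
#' @slot baseIntensity,textureContrast grayscale level of the body and the
#'   standard deviation of its internal texture.
#' @export
setClass("BodySpec",
  representation(label = "character", shape = "character", center = "numeric",
                 size = "numeric", textureSeed = "integer",
                 motionAxis = "numeric", angleAmplitude = "numeric",
                 translationAmplitude = "numeric", phaseOffset = "numeric",
                 baseIntensity = "numeric", textureContrast = "numeric"))

setValidity("BodySpec", function(object) {
  if (!object@shape %in% c("ellipsoid", "capsule", "L-prism", "arch"))
    return("unknown shape")
  if (any(object@size <= 0)) return("half-extents must be positive")
  if (abs(sqrt(sum(object@motionAxis^2)) - 1) > .unit_tol)
    return("motionAxis must be unit norm within 1e-9")
  if (object@phaseOffset < 0 || object@phaseOffset >= 1)
    return("phaseOffset must lie in [0, 1)")
  if (object@angleAmplitude < 0) return("angleAmplitude must be >= 0")
  TRUE
})

#' Construct a BodySpec
#'
#' @inheritParams rigidTransform
#' @param label,shape,center,size,textureSeed,motionAxis,angleAmplitude,translationAmplitude,phaseOffset,baseIntensity,textureContrast
#'   see the slot documentation in [BodySpec-class].
#' @return A [BodySpec-class].
#' @export
bodySpec <- function(label, shape = "ellipsoid", center, size,
                     textureSeed = 1L, motionAxis = c(0, 0, 1),
                     angleAmplitude = 0, translationAmplitude = c(0, 0, 0),
                     phaseOffset = 0, baseIntensity = 1,
                     textureContrast = 0.25) {
  motionAxis <- as.numeric(motionAxis)
  nrm <- sqrt(sum(motionAxis^2))
  if (nrm > 0) motionAxis <- motionAxis / nrm
  new("BodySpec", label = label, shape = shape, center = as.numeric(center),
      size = as.numeric(size), textureSeed = as.integer(textureSeed),
      motionAxis = motionAxis, angleAmplitude = angleAmplitude,
      translationAmplitude = as.numeric(translationAmplitude),
      phaseOffset = phaseOffset, baseIntensity = baseIntensity,
      textureContrast = textureContrast)
}

#' Specification of a synthetic 4D phantom
#'
#' @slot gridShape integer 3-vector of grid dimensions (voxels).
#' @slot voxelSize um per voxel (default 2.75).
#' @slot nPhases number of motion phases (default 10).
#' @slot bodies list of [BodySpec-class].
#' @slot background list: `intensity` (grayscale) and optional `shell`
#'   (list with center, radius, thickness, intensity) describing a static
#'   structure analogous to surrounding temporal bone.
#' @slot noiseSigma additive Gaussian noise sd (grayscale units).
#' @slot seed integer master seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nPhases = "integer", bodies = "list", background = "list",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@nPhases < 2L) return("nPhases must be >= 2")
  if (any(object@gridShape < 32L)) return("grid dimensions must be >= 32")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  for (b in object@bodies) {
    v <- validObject(b, test = TRUE)
    if (is.character(v)) return(v)
  }
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param gridShape integer 3-vector (components >= 32).
#' @param bodies list of [BodySpec-class].
#' @param voxelSize,nPhases,background,noiseSigma,seed see
#'   [PhantomSpec-class].
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape, bodies, voxelSize = 2.75, nPhases = 10L,
                        background = list(intensity = 0.2), noiseSigma = 0,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape), voxelSize = voxelSize,
      nPhases = as.integer(nPhases), bodies = bodies, background = background,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Ground-truth motion of a phantom
#'
#' @slot bodies named list, one entry per body, each a list with elements
#'   `transforms` (list of [RigidTransform-class], one per phase, expressed
#'   at the body centre), `angles` (deg, signed), `translations`
#'   (nPhases x 3 matrix, voxels) and `axis` (the prescribed unit axis).
#' @slot phaseTimes times (ms) the transforms are evaluated at.
#' @export
setClass("GroundTruth",
  representation(bodies = "list", phaseTimes = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth for", length(object@bodies), "bodies over",
      length(object@phaseTimes), "phases\n")
})

# ---------------------------------------------------------------------------
# Gating
# ---------------------------------------------------------------------------

#' Sinusoidal gating (stimulation) signal description
#'
#' @slot fStim stimulation frequency, Hz.
#' @slot tRef time (ms) of an ascending zero crossing of the stimulation
#'   sine: the reference from which phase p0 starts.
#' @export
setClass("GatingSignal", representation(fStim = "numeric", tRef = "numeric"))

setValidity("GatingSignal", function(object) {
  if (object@fStim <= 0) return("fStim must be positive")
  TRUE
})

#' Construct a GatingSignal
#' @param fStim stimulation frequency (Hz).
#' @param tRef ascending-zero-crossing reference time (ms).
#' @return A [GatingSignal-class].
#' @export
gatingSignal <- function(fStim, tRef = 0)
  new("GatingSignal", fStim = fStim, tRef = tRef)

#' Camera exposure clock
#'
#' @slot timestamps exposure-start times of each frame, ms, strictly
#'   increasing.
#' @slot exposurePeriod time between two acquisitions, ms.
#' @slot exposureTime effective photon-collection time, ms.
#' @export
setClass("FrameClock",
  representation(timestamps = "numeric", exposurePeriod = "numeric",
                 exposureTime = "numeric"))

setValidity("FrameClock", function(object) {
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (object@exposureTime > object@exposurePeriod)
    return("exposureTime must not exceed exposurePeriod")
  TRUE
})

#' Construct a FrameClock
#' @param timestamps frame exposure-start times (ms).
#' @param exposurePeriod,exposureTime acquisition period and effective
#'   exposure (ms).
#' @return A [FrameClock-class].
#' @export
frameClock <- function(timestamps, exposurePeriod, exposureTime = exposurePeriod)
  new("FrameClock", timestamps = as.numeric(timestamps),
      exposurePeriod = exposurePeriod, exposureTime = exposureTime)

#' Subdivision of one stimulation period into phase windows
#'
#' @slot fStim stimulation frequency, Hz.
#' @slot nPhases number of equal windows.
#' @slot period stimulation period, ms (1000 / fStim).
#' @slot binWidth window width, ms (period / nPhases).
#' @slot binStartTimes,binCenterTimes window start and centre times, ms.
#' @export
setClass("PhaseGrid",
  representation(fStim = "numeric", nPhases = "integer", period = "numeric",
                 binWidth = "numeric", binStartTimes = "numeric",
                 binCenterTimes = "numeric"))

setValidity("PhaseGrid", function(object) {
  if (object@nPhases < 2L) return("nPhases must be >= 2")
  if (abs(object@binWidth * object@nPhases - object@period) > 1e-9)
    return("bin widths must sum to one period within 1e-9")
  TRUE
})

#' Construct a PhaseGrid
#'
#' @param fStim stimulation frequency (Hz).
#' @param nPhases number of phase windows (default 10).
#' @return A [PhaseGrid-class]. Phase p0 starts at the ascending
#'   zero-crossing reference; window j covers
#'   `[j, j+1) * period / nPhases`.
#' @examples
#' phaseGrid(128, 10)@binWidth   # 0.78125 ms between phases
#' @export
phaseGrid <- function(fStim, nPhases = 10L) {
  nPhases <- as.integer(nPhases)
  period <- 1000 / fStim
  bw <- period / nPhases
  starts <- (seq_len(nPhases) - 1L) * bw
  new("PhaseGrid", fStim = fStim, nPhases = nPhases, period = period,
      binWidth = bw, binStartTimes = starts, binCenterTimes = starts + bw / 2)
}

#' @rdname nPhases
#' @export
setMethod("nPhases", "PhaseGrid", function(x) x@nPhases)

setMethod("show", "PhaseGrid", function(object) {
  cat("PhaseGrid:", object@nPhases, "windows of", object@binWidth,
      "ms over a", object@period, "ms period (f =", object@fStim, "Hz)\n")
})

#' Assignment of projection frames to motion phases
#'
#' @slot phase integer vector, one 0-based phase index per frame.
#' @slot nPhases number of phase bins.
#' @slot angles optional per-frame projection angles (degrees).
#' @export
setClass("PhaseAssignment",
  representation(phase = "integer", nPhases = "integer", angles = "numeric"),
  prototype(angles = numeric(0)))

setValidity("PhaseAssignment", function(object) {
  if (any(object@phase < 0L | object@phase >= object@nPhases))
    return("phase indices must lie in [0, nPhases)")
  if (length(object@angles) && length(object@angles) != length(object@phase))
    return("angles must have one entry per frame")
  TRUE
})

#' @rdname nPhases
#' @export
setMethod("nPhases", "PhaseAssignment", function(x) as.integer(x@nPhases))

setMethod("show", "PhaseAssignment", function(object) {
  cat("PhaseAssignment:", length(object@phase), "frames into",
      object@nPhases, "phases\n")
  print(tabulate(object@phase + 1L, object@nPhases))
})

# ---------------------------------------------------------------------------
# Registration inputs
# ---------------------------------------------------------------------------

#' Cuboid sub-volume inside one ossicle
#'
#' @slot label label of the ossicle the sub-volume belongs to.
#' @slot center absolute 0-based voxel coordinates (integer-valued).
#' @slot halfExtents integer 3-vector of half-extents, voxels.
#' @export
setClass("SubVolumeSpec",
  representation(label = "character", center = "numeric",
                 halfExtents = "numeric"))

setValidity("SubVolumeSpec", function(object) {
  if (any(object@halfExtents < 0)) return("halfExtents must be >= 0")
  if (any(object@center != round(object@center)) ||
      any(object@halfExtents != round(object@halfExtents)))
    return("center and halfExtents must be integer-valued (voxel lattice)")
  TRUE
})

#' Construct a SubVolumeSpec
#' @param label ossicle label.
#' @param center,halfExtents integer-valued voxel coordinates / half sizes.
#' @return A [SubVolumeSpec-class].
#' @export
subVolumeSpec <- function(label, center, halfExtents)
  new("SubVolumeSpec", label = label, center = as.numeric(center),
      halfExtents = as.numeric(halfExtents))

#' Parameters of the intensity-based rigid registration
#'
#' @slot metric "ncc" (normalized cross-correlation, default: the phantom
#'   volumes are mono-modal) or "mi" (Mattes-style mutual information with a
#'   linearly binned joint histogram, as used on beamline data).
#' @slot maxIterations optimiser iteration cap (default 1000).
#' @slot minStep minimum step length / relative tolerance (default 1e-5).
#' @slot pyramidLevels multiresolution levels (default 3).
#' @slot interpolation "cubic" (C1-smooth, default) or "linear" sampling of
#'   the moving volume during metric evaluation.
#' @slot margin voxels of context kept around the moving crop (default 8;
#'   must exceed the largest expected displacement plus interpolator
#'   support).
#' @slot smoothingSigma Gaussian pre-smoothing of both crops, voxels
#'   (default 0.8; regularizes the metric against voxel noise without
#'   biasing the optimum, since both crops are filtered identically).
#' @slot nBins histogram bins for the MI metric.
#' @export
setClass("RegistrationParams",
  representation(metric = "character", maxIterations = "integer",
                 minStep = "numeric", pyramidLevels = "integer",
                 interpolation = "character", margin = "integer",
                 smoothingSigma = "numeric", nBins = "integer"))

setValidity("RegistrationParams", function(object) {
  if (!object@metric %in% c("ncc", "mi")) return("metric must be ncc or mi")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@pyramidLevels < 1L) return("pyramidLevels must be >= 1")
  if (!object@interpolation %in% c("linear", "cubic"))
    return("interpolation must be linear or cubic")
  TRUE
})

#' Construct RegistrationParams
#' @param metric,maxIterations,minStep,pyramidLevels,interpolation,margin,smoothingSigma,nBins
#'   see [RegistrationParams-class].
#' @return A [RegistrationParams-class].
#' @export
registrationParams <- function(metric = "ncc", maxIterations = 1000L,
                               minStep = 1e-5, pyramidLevels = 3L,
                               interpolation = "cubic", margin = 8L,
                               smoothingSigma = 0.8, nBins = 32L)
  new("RegistrationParams", metric = metric,
      maxIterations = as.integer(maxIterations), minStep = minStep,
      pyramidLevels = as.integer(pyramidLevels), interpolation = interpolation,
      margin = as.integer(margin), smoothingSigma = smoothingSigma,
      nBins = as.integer(nBins))

# ---------------------------------------------------------------------------
# Kinematics
# ---------------------------------------------------------------------------

#' Outlier-rejection policy for per-sub-volume transform parameters
#'
#' A sub-volume is discarded at a phase if any of its seven parameters
#' (three translation components, three rotation-axis components, rotation
#' angle) deviates from the across-sub-volume mean by more than
#' `kSigma` standard deviations, or exceeds `kMedian` times the absolute
#' median of that parameter.
#'
#' @slot kSigma sigma multiple (default 2).
#' @slot kMedian median multiple (default 5).
#' @slot minSurvivors if fewer survive, all sub-volumes are kept and a
#'   warning flag raised (default 2).
#' @export
setClass("OutlierPolicy",
  representation(kSigma = "numeric", kMedian = "numeric",
                 minSurvivors = "integer"))

setValidity("OutlierPolicy", function(object) {
  if (object@kSigma <= 0) return("kSigma must be > 0")
  if (object@kMedian <= 1) return("kMedian must be > 1")
  TRUE
})

#' Construct an OutlierPolicy
#' @param kSigma,kMedian,minSurvivors see [OutlierPolicy-class].
#' @return An [OutlierPolicy-class].
#' @export
outlierPolicy <- function(kSigma = 2, kMedian = 5, minSurvivors = 2L)
  new("OutlierPolicy", kSigma = kSigma, kMedian = kMedian,
      minSurvivors = as.integer(minSurvivors))

#' Averaged per-phase motion of one ossicle
#'
#' @slot label ossicle label.
#' @slot origin global origin O_0 (centre of the first sub-volume).
#' @slot voxelSize um per voxel.
#' @slot svTransforms list over phases of lists over sub-volumes of
#'   [RigidTransform-class], all re-expressed at `origin`.
#' @slot survivors logical matrix (phases x sub-volumes): outlier mask.
#' @slot meanTransforms list of per-phase mean [RigidTransform-class].
#' @slot meanAxisAngles list of per-phase mean [AxisAngle-class].
#' @slot dispersions numeric matrix (phases x 7): per-parameter standard
#'   deviations across surviving sub-volumes.
#' @slot principalAxis angle-weighted mean rotation axis over phases.
#' @slot phaseTimes bin times (ms).
#' @slot warnings character vector of per-phase notes (e.g. outlier-floor
#'   pass-all events).
#' @export
setClass("OssicleMotion",
  representation(label = "character", origin = "numeric",
                 voxelSize = "numeric", svTransforms = "list",
                 survivors = "matrix", meanTransforms = "list",
                 meanAxisAngles = "list", dispersions = "matrix",
                 principalAxis = "numeric", phaseTimes = "numeric",
                 warnings = "character"))

#' @rdname nPhases
#' @export
setMethod("nPhases", "OssicleMotion", function(x) length(x@meanTransforms))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "OssicleMotion", function(x) x@voxelSize)

setMethod("show", "OssicleMotion", function(object) {
  ang <- vapply(object@meanAxisAngles, function(a) a@angle, numeric(1))
  cat("OssicleMotion '", object@label, "': ", length(ang), " phases\n",
      sep = "")
  cat("  max rotation angle: ", signif(max(ang), 4), " deg\n", sep = "")
  cat("  principal axis: (",
      paste(signif(object@principalAxis, 4), collapse = ", "), ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# Displacement
# ---------------------------------------------------------------------------

#' Set of tracked points in one region of interest
#'
#' @slot label ROI label (e.g. "umbo", "stapes_footplate").
#' @slot ossicle label of the ossicle the points belong to.
#' @slot points n x 3 matrix of absolute 0-based voxel coordinates.
#' @slot voxelSize um per voxel.
#' @export
setClass("ROIPointSet",
  representation(label = "character", ossicle = "character",
                 points = "matrix", voxelSize = "numeric"))

setValidity("ROIPointSet", function(object) {
  if (nrow(object@points) < 1L) return("need at least one point")
  if (ncol(object@points) != 3L) return("points must be n x 3")
  TRUE
})

#' Construct an ROIPointSet
#' @param label,ossicle,points,voxelSize see [ROIPointSet-class].
#' @return An [ROIPointSet-class].
#' @export
roiPointSet <- function(label, ossicle, points, voxelSize = 2.75) {
  points <- rbind(points)
  new("ROIPointSet", label = label, ossicle = ossicle,
      points = unname(as.matrix(points)), voxelSize = voxelSize)
}

#' Per-phase displacement of an ROI
#'
#' @slot roi,ossicle labels.
#' @slot times bin times, ms.
#' @slot meanDisplacement nPhases x 3 matrix of the point-averaged
#'   displacement vectors, um.
#' @slot signedNorm signed displacement norms, um (see [signedNorms()]).
#' @slot perPointNorm nPhases x nPoints matrix of per-point signed norms, um.
#' @slot sd per-phase standard deviation of the per-point norms, um.
#' @slot refDirection the unit direction used as the sign reference (the
#'   displacement direction at the phase of maximum magnitude). Flipping it
#'   flips all signs and shifts a fitted phase by half a cycle.
#' @export
setClass("DisplacementTrace",
  representation(roi = "character", ossicle = "character", times = "numeric",
                 meanDisplacement = "matrix", signedNorm = "numeric",
                 perPointNorm = "matrix", sd = "numeric",
                 refDirection = "numeric"))

setMethod("show", "DisplacementTrace", function(object) {
  cat("DisplacementTrace '", object@roi, "' (", object@ossicle, "): ",
      length(object@times), " phases, peak |D| = ",
      signif(max(abs(object@signedNorm)), 4), " um\n", sep = "")
})

#' Constrained sine fit of a displacement trace
#'
#' Model `D(t) = A * sin(2*pi*(f*t + phi))` with the stimulation frequency f
#' held fixed; only amplitude and phase are estimated.
#'
#' @slot A amplitude, um (>= 0).
#' @slot phi phase shift as a cycle fraction in [0, 1).
#' @slot f frequency, Hz (fixed).
#' @slot R2 coefficient of determination of the fit.
#' @export
setClass("SineFit",
  representation(A = "numeric", phi = "numeric", f = "numeric",
                 R2 = "numeric"))

setValidity("SineFit", function(object) {
  if (object@A < 0) return("A must be >= 0")
  if (object@phi < 0 || object@phi >= 1) return("phi must lie in [0, 1)")
  TRUE
})

setMethod("show", "SineFit", function(object) {
  cat("SineFit: A = ", signif(object@A, 6), " um (2A = ",
      signif(2 * object@A, 6), "), phi = ", signif(object@phi, 6),
      " cycles, f = ", object@f, " Hz, R2 = ", signif(object@R2, 6), "\n",
      sep = "")
})

#' Noise-floor report from a static reference region
#'
#' @slot maxTranslation max translation magnitude over phases, um.
#' @slot maxAngle max rotation angle over phases, degrees.
#' @slot maxDisplacement max induced point displacement over phases, um.
#' @slot bounds named numeric: configured bounds (translation_um, angle_deg,
#'   displacement_um).
#' @slot pass logical: all maxima within bounds.
#' @slot failed character vector naming any violated bound.
#' @export
setClass("NoiseFloorReport",
  representation(maxTranslation = "numeric", maxAngle = "numeric",
                 maxDisplacement = "numeric", bounds = "numeric",
                 pass = "logical", failed = "character"))

setMethod("show", "NoiseFloorReport", function(object) {
  cat("NoiseFloorReport:", if (object@pass) "PASS" else "FAIL", "\n")
  cat("  max |t| = ", signif(object@maxTranslation, 4), " um (bound ",
      object@bounds[["translation_um"]], ")\n", sep = "")
  cat("  max angle = ", signif(object@maxAngle, 4), " deg (bound ",
      object@bounds[["angle_deg"]], ")\n", sep = "")
  cat("  max displacement = ", signif(object@maxDisplacement, 4),
      " um (bound ", object@bounds[["displacement_um"]], ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# Planar QC
# ---------------------------------------------------------------------------

#' Intensity profile along a line, per phase
#'
#' @slot matrix intensity matrix: rows index position along the line,
#'   columns index phases.
#' @slot positions distances along the line, voxels.
#' @slot spacing sample spacing, voxels.
#' @slot voxelSize um per voxel.
#' @slot line list with `from` and `to` endpoints (voxel coordinates).
#' @export
setClass("ProfileMatrix",
  representation(matrix = "matrix", positions = "numeric",
                 spacing = "numeric", voxelSize = "numeric", line = "list"))

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@matrix), "samples x",
      ncol(object@matrix), "phases\n")
})
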