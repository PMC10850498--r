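# The canonical validation phantom: three independently moving textured
# bodies standing in for the malleus, incus and stapes, plus a static
# reference body standing in for the surrounding temporal bone, on a 144^3
# grid at 2.75 um voxels with 10 motion phases. Motion amplitudes sit in
# the ranges resolved by the imaging experiments (rotations up to ~2
# degrees, translations up to ~3 voxels); the strong internal texture
# plays the role of the ossicles' internal vascular structure, which is
# what conditions intensity-based registration.

.ossicle_bodies <- function() {
  s2 <- 1 / sqrt(2)
  list(
    bodySpec("malleus", "capsule", center = c(38, 38, 72),
             size = c(26, 26, 27), textureSeed = 101L,
             motionAxis = c(s2, s2, 0), angleAmplitude = 1.5,
             translationAmplitude = c(0.5, 0.3, 0.2),
             textureContrast = 0.4),
    bodySpec("incus", "capsule", center = c(106, 38, 72),
             size = c(26, 26, 27), textureSeed = 202L,
             motionAxis = c(0, 1, 0), angleAmplitude = 0.8,
             translationAmplitude = c(2.0, 0, 1.0),
             textureContrast = 0.4),
    bodySpec("stapes", "capsule", center = c(38, 106, 72),
             size = c(26, 26, 27), textureSeed = 303L,
             motionAxis = c(0, 0, 1), angleAmplitude = 0.3,
             translationAmplitude = c(0.8, -2.5, 0.6),
             textureContrast = 0.4),
    bodySpec("temporal", "capsule", center = c(106, 106, 72),
             size = c(20, 20, 21), textureSeed = 404L,
             motionAxis = c(0, 0, 1), angleAmplitude = 0,
             translationAmplitude = c(0, 0, 0),
             textureContrast = 0.4))
}

#' Canonical four-body validation phantom
#'
#' Three moving "ossicles" with distinct prescribed sinusoidal rigid
#' motions, plus one static reference body for noise-floor estimation.
#' The default noise level corresponds to a contrast signal-to-noise ratio
#' of 20 (sigma = body/background contrast / 20).
#'
#' @param seed master seed for the rendered noise.
#' @param noiseSigma additive Gaussian noise sd (default 0.04 = SNR 20 at
#'   the phantom's body/background contrast of 0.8).
#' @param nPhases number of motion phases (default 10).
#' @return A [PhantomSpec-class].
#' @seealso [ossicleSubVolumes()], [ossicleROIs()]
#' @export
ossiclePhantomSpec <- function(seed = 7L, noiseSigma = 0.04, nPhases = 10L) {
  phantomSpec(c(144, 144, 144), .ossicle_bodies(), voxelSize = 2.75,
              nPhases = nPhases, noiseSigma = noiseSigma, seed = seed)
}

#' Sub-volume layout for the canonical phantom
#'
#' Four cubic sub-volumes per moving body (strictly interior to the body
#' at every phase) and two for the static reference.
#'
#' @return List of [SubVolumeSpec-class].
#' @export
ossicleSubVolumes <- function() {
  svOf <- function(label, center, he = c(11, 11, 11))
    lapply(list(c(5, 0, 5), c(-5, 0, 5), c(5, 0, -5), c(-5, 0, -5)),
           function(dc) subVolumeSpec(label, center + dc, he))
  c(svOf("malleus", c(38, 38, 72)),
    svOf("incus", c(106, 38, 72)),
    svOf("stapes", c(38, 106, 72)),
    lapply(list(c(0, 0, 5), c(0, 0, -5)), function(dc)
      subVolumeSpec("temporal", c(106, 106, 72) + dc, c(9, 9, 9))))
}

#' ROI point sets for the canonical phantom
#'
#' Two regions per moving ossicle, each a small cluster of points placed
#' about 20 voxels from the body's rotation axis (lever-arm positions),
#' plus one region on the static reference body.
#'
#' @param voxelSize um per voxel (default 2.75).
#' @return Named list of [ROIPointSet-class].
#' @export
ossicleROIs <- function(voxelSize = 2.75) {
  s2 <- 1 / sqrt(2)
  cluster <- function(p)
    rbind(p, p + c(1.5, 0, 0), p + c(0, 1.5, 0), p + c(0, 0, 1.5),
          p - c(1.5, 1.5, 0))
  rois <- list(
    roiPointSet("umbo", "malleus",
                cluster(c(38, 38, 72) + 20 * c(s2, -s2, 0)), voxelSize),
    roiPointSet("malleus_IM", "malleus",
                cluster(c(38, 38, 72) + 10 * c(-s2, s2, 0)), voxelSize),
    roiPointSet("incus_IM", "incus",
                cluster(c(106, 38, 72) + c(10, 0, 0)), voxelSize),
    roiPointSet("lenticular_process", "incus",
                cluster(c(106, 38, 72) + c(-20, 0, 0)), voxelSize),
    roiPointSet("stapes_head", "stapes",
                cluster(c(38, 106, 72) + c(20, 0, 0)), voxelSize),
    roiPointSet("stapes_footplate", "stapes",
                cluster(c(38, 106, 72) + c(-20, 0, 0)), voxelSize),
    roiPointSet("temporal_ref", "temporal",
                cluster(c(106, 106, 72) + c(10, 0, 0)), voxelSize))
  stats::setNames(rois, vapply(rois, function(r) r@label, character(1)))
}

#' Ground-truth displacement trace of an ROI
#'
#' Applies the phantom's exact relative transforms (re-expressed at the
#' ROI's body centre) to the ROI points: the analytic reference against
#' which pipeline estimates are judged.
#'
#' @param truth a [GroundTruth-class].
#' @param roi an [ROIPointSet-class] whose `ossicle` names a phantom body.
#' @return A [DisplacementTrace-class].
#' @export
truthTrace <- function(truth, roi) {
  b <- truth@bodies[[roi@ossicle]]
  if (is.null(b)) stop("no ground truth for body '", roi@ossicle, "'")
  n <- length(b$transforms)
  um <- roi@voxelSize
  npts <- nrow(roi@points)
  disp <- array(0, c(n, 3, npts))
  for (j in seq_len(n)) {
    moved <- applyTransform(b$transforms[[j]], roi@points)
    disp[j, , ] <- t(moved - roi@points) * um
  }
  meanDisp <- apply(disp, c(1, 2), mean)
  signed <- .signedNormsImpl(meanDisp)
  perPoint <- matrix(0, n, npts)
  normsMean <- sqrt(rowSums(meanDisp^2))
  ref <- which.max(normsMean)
  u <- if (normsMean[ref] > 0) meanDisp[ref, ] / normsMean[ref] else c(1, 0, 0)
  for (p in seq_len(npts)) {
    dp <- disp[, , p, drop = FALSE][, , 1]
    s <- sign(dp %*% u); s[s == 0] <- 1
    perPoint[, p] <- sqrt(rowSums(dp^2)) * s
  }
  new("DisplacementTrace", roi = roi@label, ossicle = roi@ossicle,
      times = truth@phaseTimes, meanDisplacement = meanDisp,
      signedNorm = as.numeric(signed), perPointNorm = perPoint,
      sd = if (npts > 1L) apply(perPoint, 1, stats::sd) else rep(0, n),
      refDirection = attr(signed, "refDirection"))
}
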