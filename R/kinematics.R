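# Vetting and averaging of per-sub-volume rigid transforms into one mean
# transform per ossicle per phase, plus rotation-axis descriptors.

# The seven scalar parameters of a transform: translation components,
# rotation-axis components, rotation angle (degrees).
.transformParameters <- function(tr) {
  aa <- toAxisAngle(tr@rotation)
  c(tr@translation, aa@axis, aa@angle)
}

.param_names <- c("tx", "ty", "tz", "ax", "ay", "az", "angle")

#' Flag outlying sub-volume transform estimates
#'
#' A row (sub-volume) is discarded when any parameter deviates from the
#' across-sub-volume mean by more than `kSigma` standard deviations, or when
#' its absolute value exceeds `kMedian` times the absolute median of that
#' parameter (the signature of a registration that failed to converge).
#' Parameters with zero dispersion pass everyone. If fewer than
#' `minSurvivors` rows survive, all rows are kept and the `warning`
#' attribute is set.
#'
#' @param values numeric vector (one parameter) or matrix with one row per
#'   sub-volume and one column per parameter.
#' @param policy an [OutlierPolicy-class].
#' @return Logical survivor mask (one entry per row), with attribute
#'   `warning` (TRUE when the min-survivor floor forced a pass-all).
#' @examples
#' rejectOutliers(c(1.0, 1.1, 0.9, 1.05, 5.5))
#' @export
rejectOutliers <- function(values, policy = outlierPolicy()) {
  stopifnot(is(policy, "OutlierPolicy"))
  v <- rbind(values)
  if (is.vector(values)) v <- cbind(values)
  n <- nrow(v)
  if (n < 3L) {
    # with two estimates neither dispersion rule can single one out;
    # pass all and flag that the vetting was inactive
    out <- rep(TRUE, n)
    attr(out, "warning") <- n == 2L
    return(out)
  }
  keep <- rep(TRUE, n)
  for (p in seq_len(ncol(v))) {
    x <- v[, p]
    mu <- mean(x); s <- stats::sd(x)
    if (s > 0) keep <- keep & abs(x - mu) <= policy@kSigma * s
    med <- abs(stats::median(x))
    if (med > 0) keep <- keep & abs(x) <= policy@kMedian * med
  }
  warn <- FALSE
  if (sum(keep) < policy@minSurvivors) {
    keep <- rep(TRUE, n)
    warn <- TRUE
  }
  attr(keep, "warning") <- warn
  keep
}

# Flip axes to a consistent hemisphere: non-negative dot product with the
# axis at the largest angle.
.signAlignAxes <- function(axes, angles) {
  ref <- axes[which.max(angles), ]
  flip <- drop(axes %*% ref) < 0
  axes[flip, ] <- -axes[flip, ]
  axes
}

#' Average rigid transforms expressed at a common origin
#'
#' Translation and (sign-aligned) rotation-axis vectors are averaged
#' component-wise; the angle is averaged as a scalar; the mean rotation
#' matrix is rebuilt from the mean axis-angle. Dispersions are per-parameter
#' sample standard deviations.
#'
#' @param transforms list of [RigidTransform-class] at one common origin.
#' @return List with `transform` (mean [RigidTransform-class]), `axisAngle`
#'   (mean [AxisAngle-class]) and `dispersion` (named numeric length 7).
#' @export
averageTransforms <- function(transforms) {
  if (!length(transforms)) stop("cannot average an empty set of transforms")
  O <- transforms[[1L]]@origin
  for (tr in transforms)
    if (max(abs(tr@origin - O)) > 1e-9)
      stop("transforms must share one origin; re-express them first")
  P <- t(vapply(transforms, .transformParameters, numeric(7)))
  colnames(P) <- .param_names
  if (nrow(P) > 1L) P[, 4:6] <- .signAlignAxes(P[, 4:6, drop = FALSE], P[, 7])
  m <- colMeans(P)
  disp <- if (nrow(P) > 1L) apply(P, 2, stats::sd) else
    stats::setNames(rep(0, 7), .param_names)
  axis <- unname(m[4:6])
  nrm <- sqrt(sum(axis^2))
  angle <- unname(m[7])
  if (angle < 1e-6 || nrm < 1e-12) {
    aa <- new("AxisAngle", axis = c(0, 0, 1), angle = max(angle, 0),
              degenerate = TRUE)
    R <- diag(3)
  } else {
    axis <- axis / nrm
    aa <- new("AxisAngle", axis = axis, angle = angle, degenerate = FALSE)
    R <- fromAxisAngle(axis, angle)
  }
  ph <- transforms[[1L]]@phase
  list(transform = rigidTransform(R, m[1:3], O, phase = ph),
       axisAngle = aa, dispersion = disp)
}

#' Principal rotation axis over the motion cycle
#'
#' Sign-aligned, angle-weighted mean of the per-phase rotation axes,
#' renormalized. Phases whose angle is degenerate or below
#' `angleFloor * max(angle)` are excluded.
#'
#' @param axisAngles list of [AxisAngle-class], one per phase.
#' @param angleFloor fraction of the maximum angle below which a phase is
#'   excluded (default 0.1).
#' @return Unit 3-vector.
#' @export
principalRotationAxis <- function(axisAngles, angleFloor = 0.1) {
  ang <- vapply(axisAngles, function(a) a@angle, numeric(1))
  deg <- vapply(axisAngles, function(a) a@degenerate, logical(1))
  keep <- !deg & ang >= angleFloor * max(ang)
  if (!any(keep))
    stop("all phases are rotation-degenerate; no principal axis")
  axes <- t(vapply(axisAngles[keep], function(a) a@axis, numeric(3)))
  axes <- .signAlignAxes(axes, ang[keep])
  m <- colSums(axes * ang[keep]) / sum(ang[keep])
  m / sqrt(sum(m^2))
}

#' Combine per-sub-volume registrations into one ossicle's motion
#'
#' Re-expresses every sub-volume's per-phase transform at the global origin
#' (the centre of the first sub-volume), applies per-phase outlier rejection
#' to the seven transform parameters, averages the survivors, and derives
#' the principal rotation axis.
#'
#' @param svTransforms list over sub-volumes of lists over phases of
#'   [RigidTransform-class] (as returned by [registerPhaseSeries()]).
#' @param label ossicle label.
#' @param voxelSize um per voxel.
#' @param policy an [OutlierPolicy-class].
#' @param scope "per_phase" (a sub-volume may be dropped at some phases and
#'   kept at others, default) or "whole_sv" (dropped everywhere if flagged
#'   anywhere).
#' @param phaseTimes bin times (ms); defaults to j/n of a 128 Hz period.
#' @param angleFloor passed to [principalRotationAxis()].
#' @return An [OssicleMotion-class].
#' @export
ossicleMotion <- function(svTransforms, label = "ossicle", voxelSize = 2.75,
                          policy = outlierPolicy(), scope = "per_phase",
                          phaseTimes = NULL, angleFloor = 0.1) {
  scope <- match.arg(scope, c("per_phase", "whole_sv"))
  nSV <- length(svTransforms)
  stopifnot(nSV >= 1L)
  n <- length(svTransforms[[1L]])
  O0 <- svTransforms[[1L]][[1L]]@origin
  if (is.null(phaseTimes)) phaseTimes <- (seq_len(n) - 1) / n * 1000 / 128

  # re-express everything at the global origin
  perPhase <- lapply(seq_len(n), function(j)
    lapply(svTransforms, function(sv) reexpressTransform(sv[[j]], O0)))

  survivors <- matrix(TRUE, n, nSV)
  warnings <- character(0)
  for (j in seq_len(n)) {
    P <- t(vapply(perPhase[[j]], .transformParameters, numeric(7)))
    if (nSV > 1L) P[, 4:6] <- .signAlignAxes(P[, 4:6, drop = FALSE], P[, 7])
    keep <- rejectOutliers(P, policy)
    survivors[j, ] <- keep
    if (isTRUE(attr(keep, "warning")))
      warnings <- c(warnings, sprintf(
        "phase %d: outlier vetting inactive (too few sub-volumes); keeping all",
        j - 1L))
  }
  if (scope == "whole_sv") {
    globalKeep <- apply(survivors, 2, all)
    if (sum(globalKeep) < policy@minSurvivors) {
      globalKeep <- rep(TRUE, nSV)
      warnings <- c(warnings, "whole_sv scope left too few survivors; keeping all")
    }
    survivors <- matrix(rep(globalKeep, each = n), n, nSV)
  }

  meanTransforms <- vector("list", n)
  meanAxisAngles <- vector("list", n)
  dispersions <- matrix(0, n, 7, dimnames = list(NULL, .param_names))
  for (j in seq_len(n)) {
    avg <- averageTransforms(perPhase[[j]][survivors[j, ]])
    avg$transform@phase <- as.integer(j - 1L)
    meanTransforms[[j]] <- avg$transform
    meanAxisAngles[[j]] <- avg$axisAngle
    dispersions[j, ] <- avg$dispersion
  }
  principal <- tryCatch(principalRotationAxis(meanAxisAngles, angleFloor),
                        error = function(e) c(NA_real_, NA_real_, NA_real_))
  new("OssicleMotion", label = label, origin = O0, voxelSize = voxelSize,
      svTransforms = perPhase, survivors = survivors,
      meanTransforms = meanTransforms, meanAxisAngles = meanAxisAngles,
      dispersions = dispersions, principalAxis = principal,
      phaseTimes = phaseTimes, warnings = warnings)
}

#' Signed per-phase rotation angles of an ossicle
#'
#' The axis-angle magnitude is non-negative by construction; for a
#' sinusoidal rotation the sign alternates with the axis direction. Each
#' phase's angle is signed by the sense of its axis relative to the
#' principal rotation axis, giving the sinusoidal angle-versus-phase
#' profile.
#'
#' @param motion an [OssicleMotion-class].
#' @return Numeric vector of signed angles (degrees), one per phase.
#' @export
signedAngles <- function(motion) {
  stopifnot(is(motion, "OssicleMotion"))
  u <- motion@principalAxis
  vapply(motion@meanAxisAngles, function(a) {
    if (a@degenerate) return(0)
    s <- sum(a@axis * u)
    a@angle * if (s < 0) -1 else 1
  }, numeric(1))
}

#' Tabulate an ossicle's mean motion per phase
#'
#' @param motion an [OssicleMotion-class].
#' @return data.frame with phase index, bin time (ms), signed rotation angle
#'   (deg), translation magnitude (um) and per-parameter dispersions.
#' @export
motionTable <- function(motion) {
  n <- nPhases(motion)
  tmag <- vapply(motion@meanTransforms, function(tr)
    sqrt(sum(tr@translation^2)) * motion@voxelSize, numeric(1))
  data.frame(phase = seq_len(n) - 1L, t_ms = motion@phaseTimes,
             angle_deg = signedAngles(motion), translation_um = tmag,
             sd_angle_deg = motion@dispersions[, "angle"],
             n_survivors = rowSums(motion@survivors))
}
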