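# ROI displacement traces, signed norms, constrained sine fitting, and the
# static-region noise floor.

#' Track ROI points through an ossicle's mean per-phase transforms
#'
#' For each point x and phase j the displacement is
#' `d_j = (R_j %*% (x - O) + O + t_j) - x` converted to micrometres.
#' Per-point traces are averaged into the ROI trace; the per-phase standard
#' deviation across points measures the sensitivity to the manual point
#' selection.
#'
#' @param motion an [OssicleMotion-class].
#' @param roi an [ROIPointSet-class] on the same ossicle.
#' @return A [DisplacementTrace-class].
#' @export
displacePoints <- function(motion, roi) {
  stopifnot(is(motion, "OssicleMotion"), is(roi, "ROIPointSet"))
  if (!identical(roi@ossicle, motion@label))
    stop("ROI '", roi@label, "' belongs to ossicle '", roi@ossicle,
         "', not '", motion@label, "'")
  n <- nPhases(motion)
  npts <- nrow(roi@points)
  um <- motion@voxelSize
  disp <- array(0, c(n, 3, npts))          # per-phase, per-axis, per-point
  for (j in seq_len(n)) {
    moved <- applyTransform(motion@meanTransforms[[j]], roi@points)
    disp[j, , ] <- t(moved - roi@points) * um
  }
  meanDisp <- apply(disp, c(1, 2), mean)
  # sign each per-point trace by the mean trace's dominant direction so the
  # across-point dispersion is that of comparable signed quantities
  normsMean <- sqrt(rowSums(meanDisp^2))
  ref <- which.max(normsMean)
  u <- if (normsMean[ref] > 0) meanDisp[ref, ] / normsMean[ref] else c(1, 0, 0)
  perPoint <- matrix(0, n, npts)
  for (p in seq_len(npts)) {
    dp <- disp[, , p, drop = FALSE][, , 1]
    s <- sign(dp %*% u)
    s[s == 0] <- 1
    perPoint[, p] <- sqrt(rowSums(dp^2)) * s
  }
  signed <- .signedNormsImpl(meanDisp)
  new("DisplacementTrace", roi = roi@label, ossicle = motion@label,
      times = motion@phaseTimes, meanDisplacement = meanDisp,
      signedNorm = as.numeric(signed),
      perPointNorm = perPoint,
      sd = if (npts > 1L) apply(perPoint, 1, stats::sd) else rep(0, n),
      refDirection = attr(signed, "refDirection"))
}

.signedNormsImpl <- function(d) {
  norms <- sqrt(rowSums(d^2))
  if (all(norms == 0)) {
    attr(norms, "refDirection") <- c(1, 0, 0)
    return(norms)
  }
  ref <- which.max(norms)
  u <- d[ref, ] / norms[ref]
  s <- sign(drop(d %*% u))
  s[s == 0] <- 1
  out <- norms * s
  attr(out, "refDirection") <- u
  out
}

#' Signed displacement norms of a trace
#'
#' The sign of `D_j` is that of the projection of `d_j` onto the unit
#' displacement direction at the phase of maximum magnitude (which is
#' therefore positive by construction). Flipping the reference direction
#' flips all signs and shifts the fitted phase by half a cycle, leaving the
#' amplitude and R2 unchanged.
#'
#' @param trace a [DisplacementTrace-class] (or an nPhases x 3 matrix of
#'   displacement vectors).
#' @return Numeric vector of signed norms.
#' @export
signedNorms <- function(trace) {
  d <- if (is(trace, "DisplacementTrace")) trace@meanDisplacement else
    rbind(trace)
  if (nrow(d) < 3L) stop("need at least 3 phases")
  out <- .signedNormsImpl(d)
  attr(out, "refDirection") <- NULL
  as.numeric(out)
}

#' Fit the constrained sine model to a displacement series
#'
#' Model `D(t) = A * sin(2*pi*(f*t + phi))` with the stimulation frequency
#' held fixed. Because the model is linear in
#' `(A*cos(2*pi*phi), A*sin(2*pi*phi))`, the least-squares optimum over
#' (A, phi) is obtained exactly by linear regression on `sin(2*pi*f*t)` and
#' `cos(2*pi*f*t)`; A >= 0 and phi in [0, 1) are canonical
#' ((-A, phi) == (A, phi + 0.5 mod 1)).
#'
#' @param D signed displacement values (um), one per phase, or a
#'   [DisplacementTrace-class].
#' @param times bin times in ms (taken from the trace if `D` is one).
#' @param f stimulation frequency in Hz (default 128).
#' @return A [SineFit-class]. An all-zero series yields A = 0 and, by the
#'   zero-residual convention, R2 = 1.
#' @examples
#' t <- (0:9) / 10 * 1000 / 128
#' fitSine(2 * sin(2 * pi * (128 * t / 1000 + 0.25)), t)
#' @export
fitSine <- function(D, times = NULL, f = 128) {
  if (is(D, "DisplacementTrace")) {
    if (is.null(times)) times <- D@times
    D <- D@signedNorm
  }
  stopifnot(f > 0, length(D) == length(times))
  if (length(D) < 3L) stop("need at least 3 phases to fit the sine")
  w <- 2 * pi * f * times / 1000           # times in ms, f in Hz
  S <- sin(w); C <- cos(w)
  X <- cbind(S, C)
  cf <- stats::lm.fit(X, D)$coefficients   # D = a sin + b cos
  a <- cf[1]; b <- cf[2]
  A <- sqrt(a^2 + b^2)
  phi <- if (A == 0) 0 else (atan2(b, a) / (2 * pi)) %% 1
  if (phi >= 1) phi <- 0                   # %% can round up to 1 exactly
  fit <- A * sin(w + 2 * pi * phi)
  ssTot <- sum((D - mean(D))^2)
  ssRes <- sum((D - fit)^2)
  R2 <- if (ssTot == 0) 1 else 1 - ssRes / ssTot
  new("SineFit", A = unname(A), phi = unname(phi), f = f, R2 = R2)
}

#' Ratio of fitted displacement amplitudes
#'
#' @param fitHigh,fitLow [SineFit-class] objects (e.g. at the higher and
#'   lower stimulation levels).
#' @return `A_high / A_low`.
#' @export
amplitudeRatio <- function(fitHigh, fitLow) {
  stopifnot(is(fitHigh, "SineFit"), is(fitLow, "SineFit"))
  if (fitLow@A == 0) stop("reference amplitude is zero; ratio undefined")
  fitHigh@A / fitLow@A
}

#' Noise floor from a confirmed-static reference region
#'
#' Runs the motion summary of a static structure through the same
#' quantities used for the ossicles and reports the maxima over phases:
#' translation magnitude (um), rotation angle (deg) and induced point
#' displacement (um). Downstream amplitudes below `maxDisplacement` should
#' be treated as unreliable.
#'
#' @param motion an [OssicleMotion-class] extracted on the static region.
#' @param roi an [ROIPointSet-class] of representative points in the region.
#' @param bounds named numeric bounds: `translation_um`, `angle_deg`,
#'   `displacement_um` (defaults 0.2, 0.002, 0.3 - the magnitudes measured
#'   on the temporal bone in the source experiments).
#' @return A [NoiseFloorReport-class].
#' @export
noiseFloor <- function(motion, roi,
                       bounds = c(translation_um = 0.2, angle_deg = 0.002,
                                  displacement_um = 0.3)) {
  stopifnot(is(motion, "OssicleMotion"))
  um <- motion@voxelSize
  maxT <- max(vapply(motion@meanTransforms, function(tr)
    sqrt(sum(tr@translation^2)), numeric(1))) * um
  maxA <- max(vapply(motion@meanAxisAngles, function(a) a@angle, numeric(1)))
  tr <- displacePoints(motion, roi)
  maxD <- max(abs(tr@perPointNorm))
  failed <- character(0)
  if (maxT > bounds[["translation_um"]]) failed <- c(failed, "translation_um")
  if (maxA > bounds[["angle_deg"]]) failed <- c(failed, "angle_deg")
  if (maxD > bounds[["displacement_um"]]) failed <- c(failed, "displacement_um")
  new("NoiseFloorReport", maxTranslation = maxT, maxAngle = maxA,
      maxDisplacement = maxD, bounds = bounds, pass = !length(failed),
      failed = failed)
}
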