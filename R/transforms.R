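# Axis-angle algebra and rigid-transform operations.
#
# Conventions: rotations are proper (det +1) 3x3 matrices; the axis-angle
# angle is kept in [0, 180] degrees with the axis carrying the sign; the
# degenerate (near-identity) axis convention is (0, 0, 1).

.deg2rad <- pi / 180
.degenerate_angle_deg <- 1e-6

#' Convert a rotation matrix to axis-angle form
#'
#' Uses the quaternion route (Shepperd's method), which is numerically
#' stable over the whole angle range including near 0 and near 180 degrees.
#'
#' @param R 3x3 rotation matrix (orthonormal within 1e-6, det +1).
#' @return An [AxisAngle-class] with angle in degrees in [0, 180]. For
#'   angles below 1e-6 degrees the degenerate flag is set and the axis is
#'   the convention (0, 0, 1).
#' @examples
#' toAxisAngle(diag(3))
#' @export
toAxisAngle <- function(R) {
  R <- unname(as.matrix(R))
  if (!all(dim(R) == c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-6 ||
      abs(det(R) - 1) > 1e-6)
    stop("R is not a proper rotation matrix (orthonormal, det +1)")
  # rotation matrix -> unit quaternion (w, x, y, z), Shepperd's branching
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= max(R[1, 1], R[2, 2], R[3, 3])) {
    w <- sqrt(1 + tr) / 2
    q <- c(w, (R[3, 2] - R[2, 3]), (R[1, 3] - R[3, 1]),
           (R[2, 1] - R[1, 2])) / c(1, rep(4 * w, 3))
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(1 + R[i, i] - R[j, j] - R[k, k])
    v <- numeric(3)
    v[i] <- s / 2
    v[j] <- (R[j, i] + R[i, j]) / (2 * s)
    v[k] <- (R[k, i] + R[i, k]) / (2 * s)
    q <- c((R[k, j] - R[j, k]) / (2 * s), v)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q                      # angle in [0, 180]
  sin_half <- sqrt(sum(q[2:4]^2))
  angle <- 2 * atan2(sin_half, q[1]) / .deg2rad
  if (angle < .degenerate_angle_deg)
    return(new("AxisAngle", axis = c(0, 0, 1), angle = angle,
               degenerate = TRUE))
  new("AxisAngle", axis = q[2:4] / sin_half, angle = angle,
      degenerate = FALSE)
}

#' Build a rotation matrix from axis and angle
#'
#' Rodrigues' formula. `fromAxisAngle(toAxisAngle(R))` reproduces `R` to
#' 1e-9 elementwise.
#'
#' @param axis 3-vector (normalized internally; must be nonzero unless
#'   `angle` is 0).
#' @param angle rotation angle in degrees. May also be omitted when `axis`
#'   is an [AxisAngle-class] object.
#' @return 3x3 rotation matrix.
#' @examples
#' fromAxisAngle(c(0, 0, 1), 90)
#' @export
fromAxisAngle <- function(axis, angle) {
  if (is(axis, "AxisAngle")) {
    angle <- axis@angle
    axis <- axis@axis
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) {
    if (abs(angle) < .degenerate_angle_deg) return(diag(3))
    stop("zero axis with nonzero angle")
  }
  u <- axis / nrm
  th <- angle * .deg2rad
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to absolute points
#'
#' Maps each point x to `R %*% (x - origin) + origin + t`.
#'
#' @param transform a [RigidTransform-class].
#' @param points numeric 3-vector or n x 3 matrix of absolute coordinates.
#' @return Object of the same shape as `points`.
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  single <- is.null(dim(points))
  P <- rbind(points)
  O <- transform@origin
  out <- sweep(tcrossprod(sweep(P, 2, O), transform@rotation), 2,
               O + transform@translation, "+")
  if (single) drop(out) else out
}

#' Re-express a rigid transform at a different rotation centre
#'
#' The rotation is unchanged and the translation becomes
#' `t + (R - I) %*% b` with `b = newOrigin_to_old = origin_new - origin_old`
#' taken as the difference from the old origin to the new one, so that the
#' induced mapping of any absolute point is identical (uniqueness of the
#' affine transformation).
#'
#' @param transform a [RigidTransform-class] expressed at some origin O_i.
#' @param newOrigin the global origin O_0 to re-express at.
#' @return A [RigidTransform-class] at `newOrigin` inducing the same
#'   point mapping.
#' @export
reexpressTransform <- function(transform, newOrigin) {
  stopifnot(is(transform, "RigidTransform"))
  b <- as.numeric(newOrigin) - transform@origin
  tNew <- transform@translation + as.numeric((transform@rotation - diag(3)) %*% b)
  rigidTransform(transform@rotation, tNew, as.numeric(newOrigin),
                 phase = transform@phase, converged = transform@converged,
                 metricValue = transform@metricValue)
}

#' Amplify a rigid transform for visualization
#'
#' Scales the rotation angle and the translation by `k`, keeping the axis
#' and the origin. Angles exceeding 180 degrees after scaling are capped
#' with a warning. `k = 1` returns the transform unchanged.
#'
#' @param transform a [RigidTransform-class].
#' @param k positive scale factor (the study used 100 for display).
#' @return A [RigidTransform-class].
#' @export
amplifyTransform <- function(transform, k) {
  stopifnot(is(transform, "RigidTransform"), k > 0)
  aa <- toAxisAngle(transform@rotation)
  ang <- aa@angle * k
  if (ang > 180) {
    warning("amplified angle exceeds 180 degrees; capping")
    ang <- 180
  }
  R <- if (aa@degenerate) diag(3) else fromAxisAngle(aa@axis, ang)
  rigidTransform(R, transform@translation * k, transform@origin,
                 phase = transform@phase)
}

#' Acute angle between two rotation axes
#'
#' Sign-invariant: an axis and its negation describe the same line, so the
#' result is `acos(|a . b|)` in degrees, in [0, 90].
#'
#' @param a,b 3-vectors (normalized internally; must be nonzero).
#' @return Angle in degrees.
#' @export
axisAngleBetween <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < .Machine$double.eps || nb < .Machine$double.eps)
    stop("zero vector has no direction")
  d <- abs(sum(a * b)) / (na * nb)
  acos(min(1, d)) / .deg2rad
}

# Composition T2 o T1 (first T1, then T2); both re-expressed at T1's origin.
.composeTransforms <- function(t2, t1) {
  t2 <- reexpressTransform(t2, t1@origin)
  R <- t2@rotation %*% t1@rotation
  tt <- as.numeric(t2@rotation %*% t1@translation) + t2@translation
  rigidTransform(R, tt, t1@origin)
}

.invertTransform <- function(tr) {
  Rt <- t(tr@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% tr@translation), tr@origin)
}
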