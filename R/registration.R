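# Intensity-based rigid registration of sub-volumes across motion phases.
#
# The estimated transform maps the phase-p0 crop onto the phase-pj crop,
# expressed with rotation centre at the sub-volume centre. The optimiser
# works on a 6-vector (rotation vector in radians, translation in voxels)
# over a multiresolution pyramid; the similarity metric is evaluated on
# intensity-normalized crops.

# Rodrigues: rotation vector (radians) -> rotation matrix
.rotvec2mat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  u <- w / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Block-mean downsample by 2 along every axis (odd trailing voxels dropped).
.downsample2 <- function(a) {
  d2 <- dim(a) %/% 2L
  i1 <- seq(1L, 2L * d2[1], by = 2L)
  i2 <- seq(1L, 2L * d2[2], by = 2L)
  i3 <- seq(1L, 2L * d2[3], by = 2L)
  (a[i1, i2, i3, drop = FALSE] + a[i1 + 1L, i2, i3, drop = FALSE] +
   a[i1, i2 + 1L, i3, drop = FALSE] + a[i1 + 1L, i2 + 1L, i3, drop = FALSE] +
   a[i1, i2, i3 + 1L, drop = FALSE] + a[i1 + 1L, i2, i3 + 1L, drop = FALSE] +
   a[i1, i2 + 1L, i3 + 1L, drop = FALSE] +
   a[i1 + 1L, i2 + 1L, i3 + 1L, drop = FALSE]) / 8
}

.normalizeCrop <- function(a) {
  s <- stats::sd(a)
  if (s == 0) stop("constant-intensity crop: registration is ill-posed")
  (a - mean(a)) / s
}

# Separable Gaussian smoothing of a 3D array with edge replication.
.smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    f[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  d <- dim(a)
  dim(a) <- c(d[1], d[2] * d[3]); a <- conv1(a); dim(a) <- d
  a <- aperm(a, c(2, 1, 3)); d2 <- dim(a)
  dim(a) <- c(d2[1], d2[2] * d2[3]); a <- conv1(a); dim(a) <- d2
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1)); d3 <- dim(a)
  dim(a) <- c(d3[1], d3[2] * d3[3]); a <- conv1(a); dim(a) <- d3
  a <- aperm(a, c(3, 2, 1))
  array(as.numeric(a), d)
}

#' Crop a cuboid sub-volume out of a volume
#'
#' @param volume 3D numeric array.
#' @param sv a [SubVolumeSpec-class] (integer-valued centre/half-extents,
#'   0-based voxel coordinates).
#' @param grow extra voxels of context on every side (clipped to the grid
#'   only when `grow > 0`; the exact crop must lie fully inside).
#' @return The cropped array with attribute `origin`: the absolute 0-based
#'   coordinate of its first voxel.
#' @export
cropSubvolume <- function(volume, sv, grow = 0L) {
  stopifnot(is(sv, "SubVolumeSpec"))
  d <- dim(volume)
  lo <- sv@center - sv@halfExtents - grow
  hi <- sv@center + sv@halfExtents + grow
  if (grow > 0L) {
    lo <- pmax(lo, 0)
    hi <- pmin(hi, d - 1)
  } else if (any(lo < 0) || any(hi > d - 1)) {
    bad <- which(lo < 0 | hi > d - 1)[1L]
    stop("sub-volume '", sv@label, "' exceeds the grid along axis ", bad,
         " (allowed [0, ", d[bad] - 1, "], requested [", lo[bad], ", ",
         hi[bad], "])")
  }
  out <- volume[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
                drop = FALSE]
  attr(out, "origin") <- as.numeric(lo)
  out
}

# Similarity cost at one pyramid level. Returns a closure over the data.
.makeCost <- function(fixed, fixedOrigin, moving, movingOrigin, center,
                      params, order) {
  nFixed <- length(fixed)
  nbins <- params@nBins
  mi <- params@metric == "mi"
  rngF <- range(fixed)
  # costs are shifted by +1 so the optimiser's relative-tolerance stopping
  # rule keeps a sane scale when the residual metric approaches zero
  function(theta) {
    R <- .rotvec2mat(theta[1:3])
    res <- .cpp_resample_rigid(moving, dim(moving), dim(fixed),
                               fixedOrigin, movingOrigin, center,
                               R, theta[4:6], order)
    ok <- !is.na(res)
    if (sum(ok) < 0.25 * nFixed) return(10)   # left the overlap region
    if (!mi) {
      ncc <- .cpp_ncc(fixed, res)[1L]
      if (is.na(ncc)) return(10)
      return(2 - ncc)
    }
    a <- (fixed[ok] - rngF[1]) / diff(rngF) * (nbins - 1)
    b <- res[ok]
    rngM <- range(b)
    if (diff(rngM) == 0) return(10)
    b <- (b - rngM[1]) / diff(rngM) * (nbins - 1)
    h <- .cpp_joint_hist(a, b, nbins)
    p <- h / sum(h)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    1 - sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }
}

#' Register one sub-volume between two phases
#'
#' Estimates the rigid transform (rotation about the sub-volume centre plus
#' translation) that best maps the phase-p0 crop onto the phase-pj crop
#' under the chosen similarity metric, to sub-voxel precision. The moving
#' crop keeps `params@margin` voxels of context so that motions up to a few
#' voxels stay inside the sampled support; optimisation is multiresolution
#' (coarse-to-fine), initialized at the identity.
#'
#' @param vol0 the reference-phase volume (3D array).
#' @param volj the target-phase volume (same grid).
#' @param sv a [SubVolumeSpec-class].
#' @param params a [RegistrationParams-class].
#' @return A [RigidTransform-class] with origin at `sv@center`; slots
#'   `converged` and `metricValue` report the optimiser outcome (for the
#'   NCC metric, `metricValue` is the final correlation).
#' @export
registerSubvolume <- function(vol0, volj, sv, params = registrationParams()) {
  stopifnot(identical(dim(vol0), dim(volj)))
  validObject(params)
  # The fixed crop is smoothed with real neighbourhood context and then
  # trimmed to its exact extent: smoothing the bare crop would replicate
  # its boundary voxels while the resampled moving values come from
  # properly smoothed interior data, biasing the optimum by ~1e-2 voxel.
  cropSubvolume(vol0, sv)                  # validate the exact crop fits
  ctx <- max(4L, ceiling(2.5 * params@smoothingSigma))
  fixedBig <- cropSubvolume(vol0, sv, grow = ctx)
  fb <- .smooth3d(fixedBig, params@smoothingSigma)
  lo <- (sv@center - sv@halfExtents) - attr(fixedBig, "origin")
  he <- 2 * sv@halfExtents
  fixed0 <- fb[lo[1] + seq_len(he[1] + 1), lo[2] + seq_len(he[2] + 1),
               lo[3] + seq_len(he[3] + 1), drop = FALSE]
  fixedOrigin0 <- sv@center - sv@halfExtents
  moving0 <- cropSubvolume(volj, sv, grow = params@margin)
  movingOrigin0 <- attr(moving0, "origin")
  fixed0 <- .normalizeCrop(fixed0)
  moving0 <- .normalizeCrop(.smooth3d(moving0, params@smoothingSigma))
  order <- if (params@interpolation == "cubic") 3L else 1L

  theta <- rep(0, 6)
  converged <- TRUE
  value <- NA_real_
  factors <- rev(2^(seq_len(params@pyramidLevels) - 1L))
  for (f in factors) {
    fixed <- fixed0; moving <- moving0
    fo <- fixedOrigin0; mo <- movingOrigin0
    ff <- 1
    while (ff < f && all(dim(fixed) %/% 2L >= 8L)) {
      fixed <- .downsample2(fixed)
      moving <- .downsample2(moving)
      ff <- ff * 2
    }
    # absolute coordinate of a level-l voxel centre: (orig + (ff-1)/2)/ff
    fo <- (fo + (ff - 1) / 2) / ff
    mo <- (mo + (ff - 1) / 2) / ff
    cost <- .makeCost(fixed, fo, moving, mo, sv@center / ff, params, order)
    thetaL <- c(theta[1:3], theta[4:6] / ff)
    opt <- stats::optim(thetaL, cost, method = "BFGS",
                        control = list(maxit = params@maxIterations,
                                       reltol = max(1e-9, params@minStep^2),
                                       parscale = c(rep(0.01, 3), rep(0.5, 3)),
                                       ndeps = rep(1e-3, 6)))
    if (opt$value > cost(thetaL)) opt <- list(par = thetaL, value = cost(thetaL),
                                              convergence = 1L)
    theta <- c(opt$par[1:3], opt$par[4:6] * ff)
    if (f == 1L) {
      converged <- opt$convergence == 0L
      value <- 2 - opt$value
    }
  }
  rigidTransform(.rotvec2mat(theta[1:3]), theta[4:6], sv@center,
                 converged = converged, metricValue = value)
}

#' Register every sub-volume of a phase series against phase p0
#'
#' @param series a [PhaseSeries-class].
#' @param svs list of [SubVolumeSpec-class].
#' @param params a [RegistrationParams-class].
#' @return List over sub-volumes; each element a list over phases of
#'   [RigidTransform-class] (phase 0 is the exact identity).
#' @export
registerPhaseSeries <- function(series, svs, params = registrationParams()) {
  stopifnot(is(series, "PhaseSeries"))
  vol0 <- series[[1L]]
  n <- nPhases(series)
  lapply(svs, function(sv) {
    out <- vector("list", n)
    out[[1L]] <- rigidTransform(diag(3), c(0, 0, 0), sv@center, phase = 0L)
    for (j in 2:n) {
      tr <- registerSubvolume(vol0, series[[j]], sv, params)
      tr@phase <- as.integer(j - 1L)
      out[[j]] <- tr
    }
    out
  })
}
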