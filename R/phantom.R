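# Synthetic 4D phantom: textured rigid bodies in sinusoidal motion over a
# static background, with known ground-truth transforms, plus simulated
# acquisition timing. This is the test bed for every downstream stage.

# Evaluate an expression with a temporary RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Periodic zero-mean unit-sd Gaussian random field, low-pass filtered with a
# Gaussian transfer function of real-space sd `sigma` voxels (FFT route, so
# the texture tiles periodically and has no edge effects).
.gaussianRandomField <- function(dm, sigma, seed) {
  w <- .withSeed(seed, array(stats::rnorm(prod(dm)), dm))
  g1 <- function(n) {
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  G <- outer(outer(g1(dm[1]), g1(dm[2])), g1(dm[3]))
  s <- Re(stats::fft(stats::fft(w) * G, inverse = TRUE)) / prod(dm)
  s / stats::sd(s)
}

# Binary inside/outside test for the supported shapes, in body-local
# coordinates (origin at the body centre), half-extents s = (a, b, c).
.shapeMask <- function(shape, x, y, z, s) {
  a <- s[1]; b <- s[2]; c3 <- s[3]
  switch(shape,
    ellipsoid = (x / a)^2 + (y / b)^2 + (z / c3)^2 <= 1,
    capsule = {
      r <- min(a, b)
      hl <- max(c3 - r, 0)
      dz <- pmax(abs(z) - hl, 0)
      x^2 + y^2 + dz^2 <= r^2
    },
    "L-prism" = (abs(x) <= a & abs(y) <= b & z <= 0 & z >= -c3) |
                (x <= 0 & x >= -a & abs(y) <= b & abs(z) <= c3),
    arch = {
      rout <- min(a, c3)
      rin <- 0.5 * rout
      rr <- sqrt(x^2 + z^2)
      abs(y) <= b & z >= 0 & rr >= rin & rr <= rout
    },
    stop("unknown shape: ", shape))
}

.template_pad <- 4L

# Textured template volume of one body at its neutral pose, plus a soft
# support mask. Returned with the absolute coordinate of its (0,0,0) voxel.
.bodyTemplate <- function(body) {
  sz <- ceiling(body@size)
  td <- 2L * (sz + .template_pad) + 1L
  lc <- lapply(1:3, function(k) seq_len(td[k]) - 1 - (sz[k] + .template_pad))
  X <- array(rep(lc[[1]], times = td[2] * td[3]), td)
  Y <- array(rep(rep(lc[[2]], each = td[1]), times = td[3]), td)
  Z <- array(rep(lc[[3]], each = td[1] * td[2]), td)
  mask <- .shapeMask(body@shape, X, Y, Z, body@size) * 1.0
  dim(mask) <- td
  # soften the boundary (~0.7 voxel) so sub-voxel motion renders smoothly
  g1 <- function(n) {
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * pi^2 * 0.7^2 * f^2)
  }
  G <- outer(outer(g1(td[1]), g1(td[2])), g1(td[3]))
  mask <- Re(stats::fft(stats::fft(mask) * G, inverse = TRUE)) / prod(td)
  mask <- pmin(pmax(mask, 0), 1)
  tex <- body@baseIntensity +
    body@textureContrast * .gaussianRandomField(td, 2, body@textureSeed)
  list(intensity = tex, alpha = mask, dim = td,
       origin = body@center - (sz + .template_pad))
}

# Ground-truth sinusoid of one body, evaluated at cycle fraction u.
.bodyPose <- function(body, u) {
  s <- sin(2 * pi * (u + body@phaseOffset))
  list(angle = body@angleAmplitude * s,
       translation = body@translationAmplitude * s)
}

# Absolute pose transform of a body at cycle fraction u (origin = centre).
.bodyPoseTransform <- function(body, u, phase = NA_integer_) {
  p <- .bodyPose(body, u)
  rigidTransform(fromAxisAngle(body@motionAxis, p$angle), p$translation,
                 body@center, phase = phase)
}

#' Generate a synthetic phase-volume series with known ground truth
#'
#' Renders each body at every phase by resampling its frozen textured
#' template through the phase's rigid pose (tricubic interpolation),
#' composited over a static background. Phase j is taken at within-cycle
#' time fraction j / nPhases, so the phase-0 pose of a body with zero phase
#' offset is its neutral pose and the ground-truth transform at phase 0 is
#' the identity.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `series` (a [PhaseSeries-class]) and
#'   `truth` (a [GroundTruth-class] whose per-body `transforms` are the
#'   phase-p0-to-phase-pj relative transforms expressed at the body centre).
#' @examples
#' sp <- phantomSpec(c(48, 48, 48), list(
#'   bodySpec("b", "ellipsoid", center = c(24, 24, 24), size = c(10, 8, 9),
#'            translationAmplitude = c(1, 0, 0))), nPhases = 4)
#' ph <- generatePhaseVolumes(sp)
#' nPhases(ph$series)
#' @export
generatePhaseVolumes <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  gd <- spec@gridShape
  n <- spec@nPhases
  period <- 1000 / 128                       # informational; times below
  bg <- array(spec@background$intensity, gd)
  sh <- spec@background$shell
  if (!is.null(sh)) {
    cc <- sh$center
    x <- (seq_len(gd[1]) - 1) - cc[1]
    y <- (seq_len(gd[2]) - 1) - cc[2]
    z <- (seq_len(gd[3]) - 1) - cc[3]
    R2 <- sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))
    bg[abs(R2 - sh$radius) <= sh$thickness / 2] <- sh$intensity
  }

  # bounds check first: every body inside the grid at every phase
  for (b in spec@bodies) {
    ext <- b@size + 2
    corners <- as.matrix(expand.grid(c(-1, 1) * ext[1], c(-1, 1) * ext[2],
                                     c(-1, 1) * ext[3]))
    corners <- sweep(corners, 2, b@center, "+")
    for (j in seq_len(n) - 1L) {
      tr <- .bodyPoseTransform(b, j / n)
      cj <- applyTransform(tr, corners)
      if (any(cj < 0) || any(sweep(cj, 2, gd - 1) > 0))
        stop("body '", b@label, "' leaves the grid at phase ", j)
    }
  }

  templates <- lapply(spec@bodies, .bodyTemplate)
  volumes <- vector("list", n)
  truthBodies <- stats::setNames(vector("list", length(spec@bodies)),
                                 vapply(spec@bodies, function(b) b@label,
                                        character(1)))
  for (bi in seq_along(spec@bodies)) {
    b <- spec@bodies[[bi]]
    t0 <- .bodyPoseTransform(b, 0, phase = 0L)
    rel <- vector("list", n)
    angles <- numeric(n)
    translations <- matrix(0, n, 3)
    for (j in seq_len(n) - 1L) {
      p <- .bodyPose(b, j / n)
      angles[j + 1L] <- p$angle
      translations[j + 1L, ] <- p$translation
      tj <- .bodyPoseTransform(b, j / n, phase = as.integer(j))
      rj <- .composeTransforms(tj, .invertTransform(t0))
      rj@phase <- as.integer(j)
      rel[[j + 1L]] <- rj
    }
    truthBodies[[bi]] <- list(transforms = rel, angles = angles,
                              translations = translations,
                              axis = b@motionAxis, center = b@center)
  }

  for (j in seq_len(n) - 1L) {
    vol <- bg
    for (bi in seq_along(spec@bodies)) {
      b <- spec@bodies[[bi]]
      tmpl <- templates[[bi]]
      tr <- .bodyPoseTransform(b, j / n)
      # output bounding box: transformed template corners, padded
      ext <- ceiling(b@size) + .template_pad
      corners <- as.matrix(expand.grid(c(-1, 1) * ext[1], c(-1, 1) * ext[2],
                                       c(-1, 1) * ext[3]))
      corners <- applyTransform(tr, sweep(corners, 2, b@center, "+"))
      lo <- pmax(floor(apply(corners, 2, min)) - 1, 0)
      hi <- pmin(ceiling(apply(corners, 2, max)) + 1, gd - 1)
      od <- as.integer(hi - lo + 1)
      # sample the template through the inverse pose
      Rinv <- t(tr@rotation)
      tinv <- -as.numeric(Rinv %*% tr@translation)
      alpha <- .cpp_resample_rigid(tmpl$alpha, as.integer(tmpl$dim), od,
                                   as.numeric(lo), tmpl$origin, b@center,
                                   Rinv, tinv, 3L)
      tex <- .cpp_resample_rigid(tmpl$intensity, as.integer(tmpl$dim), od,
                                 as.numeric(lo), tmpl$origin, b@center,
                                 Rinv, tinv, 3L)
      alpha[is.na(alpha)] <- 0
      alpha <- pmin(pmax(alpha, 0), 1)
      tex[is.na(tex)] <- 0
      ix <- lo[1]:hi[1] + 1L; iy <- lo[2]:hi[2] + 1L; iz <- lo[3]:hi[3] + 1L
      vol[ix, iy, iz] <- vol[ix, iy, iz] * (1 - alpha) + tex * alpha
    }
    if (spec@noiseSigma > 0)
      vol <- addNoise(vol, spec@noiseSigma, seed = spec@seed + j)
    volumes[[j + 1L]] <- vol
  }

  times <- (seq_len(n) - 1L) / n * period
  series <- phaseSeries(volumes, voxelSize = spec@voxelSize, fStim = 128,
                        phaseTimes = times)
  truth <- new("GroundTruth", bodies = truthBodies, phaseTimes = times)
  list(series = series, truth = truth)
}

#' Mask of voxels that any moving body can touch
#'
#' Union over phases and bodies of the (padded) axis-aligned bounding boxes
#' of the transformed body templates. Outside this mask, noiseless phase
#' volumes are voxel-for-voxel identical to phase 0.
#'
#' @param spec a [PhantomSpec-class].
#' @return Logical array of the grid shape.
#' @export
movingMask <- function(spec) {
  gd <- spec@gridShape
  mask <- array(FALSE, gd)
  n <- spec@nPhases
  for (b in spec@bodies) {
    ext <- ceiling(b@size) + .template_pad
    corners0 <- as.matrix(expand.grid(c(-1, 1) * ext[1], c(-1, 1) * ext[2],
                                      c(-1, 1) * ext[3]))
    corners0 <- sweep(corners0, 2, b@center, "+")
    for (j in seq_len(n) - 1L) {
      tr <- .bodyPoseTransform(b, j / n)
      cj <- applyTransform(tr, corners0)
      lo <- pmax(floor(apply(cj, 2, min)) - 1, 0)
      hi <- pmin(ceiling(apply(cj, 2, max)) + 1, gd - 1)
      mask[lo[1]:hi[1] + 1L, lo[2]:hi[2] + 1L, lo[3]:hi[3] + 1L] <- TRUE
    }
  }
  mask
}

#' Add reproducible Gaussian noise to a volume
#'
#' @param volume numeric array.
#' @param noiseSigma noise standard deviation (grayscale units, >= 0).
#' @param seed integer seed; the same seed gives the same noise field.
#' @return Array of the same shape.
#' @export
addNoise <- function(volume, noiseSigma, seed = 1L) {
  stopifnot(noiseSigma >= 0)
  if (noiseSigma == 0) return(volume)
  volume + .withSeed(seed, array(stats::rnorm(length(volume), 0, noiseSigma),
                                 dim(volume)))
}

#' Noise sigma corresponding to a target phantom SNR
#'
#' SNR is defined as the body-to-background intensity contrast divided by
#' the additive noise standard deviation.
#'
#' @param spec a [PhantomSpec-class].
#' @param snr target signal-to-noise ratio.
#' @return Numeric noise sigma in grayscale units.
#' @export
phantomNoiseSigma <- function(spec, snr) {
  contrast <- mean(vapply(spec@bodies, function(b) b@baseIntensity,
                          numeric(1))) - spec@background$intensity
  contrast / snr
}

#' Simulate camera exposure timing against a gating sine
#'
#' Frame i (0-based) starts at `t0 + i * exposurePeriod` ms, with optional
#' Gaussian start-time jitter. The gating signal is the stimulation sine
#' with an ascending zero crossing at `t0`.
#'
#' @param nFrames number of frames.
#' @param exposurePeriod time between acquisitions, ms (default 0.5: a
#'   2 kHz frame clock).
#' @param exposureTime effective photon-collection time, ms; must not
#'   exceed `exposurePeriod`.
#' @param fStim stimulation frequency, Hz (default 128).
#' @param t0 first exposure time, ms.
#' @param jitterSd timestamp jitter sd, ms.
#' @param seed RNG seed for the jitter.
#' @return List with `clock` ([FrameClock-class]) and `gating`
#'   ([GatingSignal-class]).
#' @examples
#' tm <- generateTiming(40000)
#' max(tm$clock@timestamps)   # 19999.5 ms: a 20 s acquisition
#' @export
generateTiming <- function(nFrames, exposurePeriod = 0.5,
                           exposureTime = 0.495, fStim = 128, t0 = 0,
                           jitterSd = 0, seed = 1L) {
  if (exposureTime > exposurePeriod)
    stop("exposureTime must not exceed exposurePeriod")
  if (exposureTime <= 0 || fStim <= 0)
    stop("exposureTime and fStim must be positive")
  ts <- t0 + (seq_len(nFrames) - 1) * exposurePeriod
  if (jitterSd > 0)
    ts <- ts + .withSeed(seed, stats::rnorm(nFrames, 0, jitterSd))
  list(clock = frameClock(ts, exposurePeriod, exposureTime),
       gating = gatingSignal(fStim, tRef = t0))
}
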