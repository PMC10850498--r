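# Planar quality-control analyses: intensity-profile-versus-phase matrices
# with extreme-position shift estimation, and standard-deviation projections
# that highlight moving features.

# Trilinear sampling of a 3D volume at arbitrary 0-based points (n x 3).
.sampleTrilinear <- function(vol, pts) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (any(x < 0 | y < 0 | z < 0 | x > d[1] - 1 | y > d[2] - 1 | z > d[3] - 1))
    stop("sample point outside the volume")
  i0 <- pmin(floor(x), d[1] - 2); j0 <- pmin(floor(y), d[2] - 2)
  k0 <- pmin(floor(z), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  at <- function(di, dj, dk)
    vol[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
  fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
        fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}

#' Intensity profile along a line, extracted for each phase
#'
#' @param series a [PhaseSeries-class].
#' @param from,to line endpoints, absolute 0-based voxel coordinates.
#' @param spacing sample spacing along the line, voxels (default 1).
#' @return A [ProfileMatrix-class]: one column per phase.
#' @export
profileOverPhases <- function(series, from, to, spacing = 1) {
  stopifnot(is(series, "PhaseSeries"), spacing > 0)
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  if (len == 0) stop("line endpoints coincide")
  pos <- seq(0, len, by = spacing)
  u <- (to - from) / len
  pts <- sweep(outer(pos, u), 2, from, "+")
  n <- nPhases(series)
  m <- matrix(0, length(pos), n)
  for (j in seq_len(n)) m[, j] <- .sampleTrilinear(series[[j]], pts)
  new("ProfileMatrix", matrix = m, positions = pos, spacing = spacing,
      voxelSize = voxelSize(series), line = list(from = from, to = to))
}

# Best lag between two profiles: cross-correlation of the spatial
# derivatives (edges become localized peaks, so the correlation peak is
# sharp even for monotone edge profiles) at integer lags, then continuous
# refinement of the lag against a linearly interpolated profile.
.profileShift <- function(a, b, maxLag) {
  da <- diff(a) - mean(diff(a))
  db <- diff(b) - mean(diff(b))
  m <- length(da)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) return(list(shift = 0, peak = 0))
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(L) {
    ia <- max(1, 1 - L):min(m, m - L)
    sum(da[ia] * db[ia + L]) / den
  }, numeric(1))
  k <- which.max(cc)
  L0 <- lags[k]
  negc <- function(s) {
    ia <- which((1:m) + s >= 1 & (1:m) + s <= m)
    bb <- stats::approx(seq_len(m), db, xout = ia + s)$y
    d2 <- sqrt(sum(da[ia]^2) * sum(bb^2))
    if (d2 == 0) 0 else -sum(da[ia] * bb) / d2
  }
  opt <- stats::optimize(negc, c(L0 - 1, L0 + 1))
  list(shift = opt$minimum, peak = -opt$objective)
}

#' Shift between the two extreme positions of a moving profile
#'
#' Cross-correlates every pair of phase profiles, picks the pair with the
#' largest mutual shift (the two extreme positions of the motion cycle),
#' and returns the sub-sample shift between them.
#'
#' @param pm a [ProfileMatrix-class] with at least 2 phases.
#' @param maxLag largest integer lag searched (default half the profile).
#' @return List with `shift_um`, `shift_voxels` (signed: later extreme
#'   phase relative to earlier one), and `phases` (the 0-based indices of
#'   the two extreme phases).
#' @export
extremeShift <- function(pm, maxLag = NULL) {
  stopifnot(is(pm, "ProfileMatrix"))
  M <- pm@matrix
  n <- ncol(M)
  if (n < 2L) stop("need at least 2 phases")
  if (max(apply(M, 2, stats::sd)) == 0)
    stop("flat profiles carry no features to correlate")
  if (is.null(maxLag)) maxLag <- max(2L, nrow(M) %/% 2L)
  best <- list(shift = 0); bi <- c(1L, 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- .profileShift(M[, i], M[, j], maxLag)
    if (abs(s$shift) > abs(best$shift)) {
      best <- s; bi <- c(i, j)
    }
  }
  sv <- best$shift * pm@spacing
  list(shift_um = sv * pm@voxelSize, shift_voxels = sv, phases = bi - 1L)
}

#' Standard-deviation projection across phases
#'
#' Per-pixel sample standard deviation (n-1 denominator) of a stack of
#' co-registered 2D reslices, one per phase. Static pixels project to
#' exactly zero; moving edges light up.
#'
#' @param slices a list of equal-size 2D matrices, or a 3D array whose
#'   third index is the phase.
#' @return 2D matrix of standard deviations.
#' @export
stdProjection <- function(slices) {
  if (is.list(slices)) {
    d <- dim(slices[[1L]])
    slices <- array(unlist(slices), c(d, length(slices)))
  }
  stopifnot(length(dim(slices)) == 3L)
  if (dim(slices)[3] < 2L) stop("need at least 2 phases")
  apply(slices, c(1, 2), stats::sd)
}

#' Extract one reslice plane from every phase volume
#'
#' @param series a [PhaseSeries-class].
#' @param plane "xy", "xz" or "yz".
#' @param index 0-based index of the fixed coordinate.
#' @return List of 2D matrices, one per phase.
#' @export
resliceSeries <- function(series, plane = c("xy", "xz", "yz"), index) {
  plane <- match.arg(plane)
  stopifnot(is(series, "PhaseSeries"))
  i <- index + 1L
  lapply(seq_len(nPhases(series)), function(j) {
    v <- series[[j]]
    switch(plane, xy = v[, , i], xz = v[, i, ], yz = v[i, , ])
  })
}
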