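# Synthetic membrane series: a smooth intensity edge at position
# pos_j = x0 + a * sin(2*pi*j/n) along x, constant in y and z.
.membraneSeries <- function(n = 10, x0 = 20, a = 0.8, dims = c(48, 16, 16)) {
  vols <- lapply(0:(n - 1), function(j) {
    pos <- x0 + a * sin(2 * pi * j / n)
    prof <- 1 / (1 + exp(-((seq_len(dims[1]) - 1) - pos) / 1.5))
    array(rep(prof, times = dims[2] * dims[3]), dims)
  })
  phaseSeries(vols, voxelSize = 2.75)
}

test_that("profiles are per-phase line samples with exact static behaviour", {
  ser <- .membraneSeries(a = 0)
  pm <- profileOverPhases(ser, from = c(2, 8, 8), to = c(45, 8, 8))
  expect_identical(ncol(pm@matrix), 10L)
  for (j in 2:10) expect_equal(pm@matrix[, j], pm@matrix[, 1])

  one <- phaseSeries(list(array(stats::runif(27), c(3, 3, 3))))
  pm1 <- profileOverPhases(one, c(0, 1, 1), c(2, 1, 1))
  expect_identical(ncol(pm1@matrix), 1L)

  expect_error(profileOverPhases(ser, c(-5, 8, 8), c(45, 8, 8)), "outside")
})

test_that("a translating edge traces a sinusoid in the profile matrix", {
  a <- 1.2
  ser <- .membraneSeries(a = a)
  pm <- profileOverPhases(ser, from = c(5, 8, 8), to = c(40, 8, 8),
                          spacing = 0.5)
  # edge position per phase = midpoint crossing of the sigmoid
  pos <- apply(pm@matrix, 2, function(p)
    stats::approx(p, pm@positions, xout = 0.5)$y)
  resid <- pos - (mean(pos) + a * sin(2 * pi * (0:9) / 10))
  expect_lt(max(abs(resid)), 0.05)
})

test_that("extreme shift finds the two extreme phases with sub-voxel accuracy", {
  a <- 0.8
  ser <- .membraneSeries(a = a)
  pm <- profileOverPhases(ser, from = c(5, 8, 8), to = c(40, 8, 8))
  es <- extremeShift(pm)
  # extreme sampled positions are a*sin at phases {2,3} and {7,8}
  trueShift <- 2 * a * sin(2 * pi * 2 / 10)     # 1.522 voxels
  expect_lt(abs(abs(es$shift_voxels) - trueShift), 0.1)
  expect_equal(abs(es$shift_um), abs(es$shift_voxels) * 2.75)
  # extremes are around phases 2-3 and 7-8 (sin extremes at j=2.5, 7.5)
  expect_true(all(es$phases %in% c(2, 3, 7, 8)))

  # integer-shift case: columns shifted by exactly 3 samples
  prof <- exp(-((1:60) - 30)^2 / 18)
  m <- cbind(prof, c(rep(0, 3), prof[1:57]))
  pmInt <- new("ProfileMatrix", matrix = m, positions = 0:59, spacing = 1,
               voxelSize = 2.75, line = list())
  esInt <- extremeShift(pmInt)
  expect_equal(abs(esInt$shift_voxels), 3, tolerance = 0.02)
  expect_equal(abs(esInt$shift_um), 8.25, tolerance = 0.1)

  # identical profiles: zero shift; flat profiles: rejected
  pmSame <- new("ProfileMatrix", matrix = cbind(prof, prof), positions = 0:59,
                spacing = 1, voxelSize = 2.75, line = list())
  expect_equal(extremeShift(pmSame)$shift_voxels, 0, tolerance = 1e-3)
  pmFlat <- new("ProfileMatrix", matrix = matrix(1, 10, 3), positions = 0:9,
                spacing = 1, voxelSize = 2.75, line = list())
  expect_error(extremeShift(pmFlat), "flat")
})

test_that("std projection is exact, order-invariant and scales linearly", {
  # static stack projects to zero everywhere
  s <- replicate(5, matrix(3, 4, 4), simplify = FALSE)
  expect_equal(stdProjection(s), matrix(0, 4, 4))

  # pixel series 0..9: sample sd = sqrt(sum((x-4.5)^2)/9)
  st <- lapply(0:9, function(j) matrix(j, 2, 2))
  expect_equal(stdProjection(st)[1, 1], stats::sd(0:9))
  expect_equal(stats::sd(0:9), 3.0276504, tolerance = 1e-6)

  set.seed(3)
  arr <- array(stats::runif(4 * 4 * 6), c(4, 4, 6))
  p1 <- stdProjection(arr)
  p2 <- stdProjection(arr[, , sample(6)])
  expect_equal(p1, p2)
  expect_equal(stdProjection(arr * 7), 7 * p1)

  expect_error(stdProjection(arr[, , 1, drop = FALSE]), "2 phases")
})

test_that("moving-body reslices light up only along moving structure", {
  sp <- phantomSpec(c(64, 64, 64), list(
    bodySpec("osc", "ellipsoid", center = c(24, 32, 32), size = c(10, 9, 9),
             textureSeed = 4L, translationAmplitude = c(2, 0, 0))),
    nPhases = 6L, seed = 2L)
  ph <- generatePhaseVolumes(sp)
  slices <- resliceSeries(ph$series, "xy", 32)
  sd2 <- stdProjection(slices)
  mask2 <- movingMask(sp)[, , 33]
  expect_equal(max(sd2[!mask2]), 0)
  expect_gt(max(sd2[mask2]), 0.01)
})
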