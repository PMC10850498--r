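test_that("zero-motion phantom yields identity truth and static volumes", {
  sp <- smallBodyPhantom(nPhases = 4L)
  ph <- generatePhaseVolumes(sp)
  expect_equal(nPhases(ph$series), 4L)
  for (j in 2:4) {
    expect_equal(ph$series[[j]], ph$series[[1]])
    tr <- ph$truth@bodies$body$transforms[[j]]
    expect_equal(tr@rotation, diag(3), tolerance = 1e-12)
    expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("ground-truth transforms follow the prescribed sinusoid", {
  sp <- smallBodyPhantom(translationAmplitude = c(2, 0, 0), nPhases = 10L)
  ph <- generatePhaseVolumes(sp)
  for (j in 0:9) {
    tr <- ph$truth@bodies$body$transforms[[j + 1]]
    expect_equal(tr@translation[1], 2 * sin(2 * pi * j / 10),
                 tolerance = 1e-12)
    expect_equal(tr@translation[2:3], c(0, 0), tolerance = 1e-12)
  }
  expect_equal(ph$truth@bodies$body$transforms[[1]]@rotation, diag(3))

  # rotation amplitude follows the same sinusoid, about the prescribed axis
  sp <- smallBodyPhantom(angleAmplitude = 1.2, motionAxis = c(0, 1, 0),
                         nPhases = 10L)
  ph <- generatePhaseVolumes(sp)
  for (j in c(1, 2, 3)) {
    aa <- toAxisAngle(ph$truth@bodies$body$transforms[[j + 1]]@rotation)
    expect_equal(aa@angle, 1.2 * sin(2 * pi * j / 10), tolerance = 1e-9)
    expect_lt(axisAngleBetween(aa@axis, c(0, 1, 0)), 1e-6)
  }
})

test_that("phase volumes differ from phase 0 only inside the moving mask", {
  sp <- phantomSpec(c(64, 64, 64), list(
    bodySpec("a", "ellipsoid", center = c(20, 20, 32), size = c(9, 8, 9),
             textureSeed = 1L, translationAmplitude = c(1.5, 0, 0)),
    bodySpec("b", "capsule", center = c(44, 40, 32), size = c(8, 8, 10),
             textureSeed = 2L, motionAxis = c(1, 0, 0),
             angleAmplitude = 1.5),
    bodySpec("c", "L-prism", center = c(24, 46, 30), size = c(8, 6, 8),
             textureSeed = 3L, translationAmplitude = c(0, 0.8, 0.8))),
    nPhases = 5L, seed = 7L)
  ph <- generatePhaseVolumes(sp)
  mask <- movingMask(sp)
  for (j in 2:5) {
    diff <- ph$series[[j]] != ph$series[[1]]
    expect_false(any(diff & !mask))
    expect_true(any(diff))
  }
})

test_that("all four body shapes render as solid textured regions", {
  for (shape in c("ellipsoid", "capsule", "L-prism", "arch")) {
    sp <- smallBodyPhantom(shape = shape, nPhases = 2L)
    ph <- generatePhaseVolumes(sp)
    v <- ph$series[[1]]
    inside <- v > 0.6      # body base intensity 1 vs background 0.2
    expect_gt(mean(inside), 0.005)
    expect_gt(stats::sd(v[inside]), 0.1)   # internal texture present
  }
})

test_that("a body leaving the grid is rejected with body and phase named", {
  sp <- phantomSpec(c(64, 64, 64), list(
    bodySpec("runaway", "ellipsoid", center = c(10, 32, 32),
             size = c(6, 6, 6), textureSeed = 1L,
             translationAmplitude = c(-3, 0, 0))),
    nPhases = 10L)
  expect_error(generatePhaseVolumes(sp), "runaway.*phase [0-9]")
})

test_that("additive noise is reproducible and calibrated", {
  v <- array(0.5, c(50, 50, 50))
  expect_identical(addNoise(v, 0), v)
  n1 <- addNoise(v, 0.1, seed = 9L)
  n2 <- addNoise(v, 0.1, seed = 9L)
  expect_identical(n1, n2)
  expect_false(identical(n1, addNoise(v, 0.1, seed = 10L)))
  # law of large numbers: sample sd within 2% on >= 1e5 voxels
  expect_equal(stats::sd(n1 - v), 0.1, tolerance = 0.02)
})

test_that("exposure timing reproduces the acquisition arithmetic", {
  tm <- generateTiming(40000, exposurePeriod = 0.5, fStim = 128, t0 = 0)
  expect_equal(max(tm$clock@timestamps), 19999.5)
  expect_equal(diff(range(tm$clock@timestamps)) + 0.5, 20000)  # 20 s span
  expect_equal(tm$gating@fStim, 128)
  expect_equal(tm$gating@tRef, 0)

  expect_true(exposureWithinPhaseWindow(tm$clock, tm$gating, 10))
  wide <- generateTiming(10, exposurePeriod = 1, exposureTime = 0.9)
  expect_false(exposureWithinPhaseWindow(wide$clock, wide$gating, 10))

  one <- generateTiming(1, t0 = 3.25)
  expect_equal(one$clock@timestamps, 3.25)

  expect_error(generateTiming(10, exposurePeriod = 0.5, exposureTime = 0.6),
               "exceed")
})

test_that("timing jitter is seeded and preserves monotonicity", {
  tm1 <- generateTiming(1000, jitterSd = 0.01, seed = 4L)
  tm2 <- generateTiming(1000, jitterSd = 0.01, seed = 4L)
  expect_identical(tm1$clock@timestamps, tm2$clock@timestamps)
  expect_true(all(diff(tm1$clock@timestamps) > 0))
})
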