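# Helpers building OssicleMotion objects directly from exact transforms.
.motionFromTransforms <- function(transforms, label = "oss",
                                  voxelSize = 2.75) {
  ossicleMotion(list(transforms), label = label, voxelSize = voxelSize)
}

.sinusoidMotion <- function(n = 10, amp = c(1, 0, 0), axis = c(0, 0, 1),
                            angleAmp = 0, origin = c(0, 0, 0)) {
  .motionFromTransforms(lapply(1:n, function(j) {
    s <- sin(2 * pi * (j - 1) / n)
    rigidTransform(fromAxisAngle(axis, angleAmp * s), amp * s, origin,
                   phase = as.integer(j - 1))
  }))
}

test_that("identity transforms give an all-zero trace", {
  mot <- .sinusoidMotion(amp = c(0, 0, 0))
  roi <- roiPointSet("r", "oss", rbind(c(3, 4, 5), c(6, 7, 8)))
  tr <- displacePoints(mot, roi)
  expect_equal(max(abs(tr@meanDisplacement)), 0)
  expect_equal(tr@signedNorm, rep(0, 10))
})

test_that("pure translation displaces every point identically, in um", {
  mot <- .sinusoidMotion(amp = c(1, 0, 0))
  roi <- roiPointSet("r", "oss", rbind(c(3, 4, 5), c(20, -7, 8), c(0, 0, 0)))
  tr <- displacePoints(mot, roi)
  expect_equal(tr@sd, rep(0, 10), tolerance = 1e-12)
  expect_equal(max(abs(tr@signedNorm)), 2.75 * sin(2 * pi * 2 / 10),
               tolerance = 1e-9)
  expect_equal(tr@meanDisplacement[, 2:3], matrix(0, 10, 2))
  expect_error(displacePoints(mot, roiPointSet("r", "other", c(1, 1, 1))),
               "belongs")
})

test_that("rotation about an axis through a point leaves that point still", {
  origin <- c(10, 10, 10)
  mot <- .sinusoidMotion(angleAmp = 2, axis = c(0, 0, 1), amp = c(0, 0, 0),
                         origin = origin)
  onAxis <- roiPointSet("axis", "oss", rbind(origin + c(0, 0, 15)))
  distal <- roiPointSet("tip", "oss", rbind(origin + c(25, 0, 0)))
  trA <- displacePoints(mot, onAxis)
  trD <- displacePoints(mot, distal)
  expect_lt(max(abs(trA@signedNorm)), 1e-9)
  expect_gt(max(abs(trD@signedNorm)), 1)      # lever arm moves
})

test_that("signed norms form a clean sinusoid for collinear displacement", {
  n <- 10
  d <- outer(sin(2 * pi * (0:9) / n), c(2, 1, -1))
  s <- signedNorms(d)
  expect_equal(s, sin(2 * pi * (0:9) / n) * sqrt(6), tolerance = 1e-9)
  expect_equal(signedNorms(matrix(0, 5, 3)), rep(0, 5))
  expect_error(signedNorms(matrix(0, 2, 3)), "3 phases")
})

test_that("the constrained sine fit recovers its own samples exactly", {
  t <- (0:9) / 10 * 1000 / 128
  D <- 2 * sin(2 * pi * (128 * t / 1000 + 0.25))
  ft <- fitSine(D, t, 128)
  expect_equal(ft@A, 2, tolerance = 1e-9)
  expect_equal(ft@phi, 0.25, tolerance = 1e-9)
  expect_equal(ft@R2, 1, tolerance = 1e-9)

  z <- fitSine(rep(0, 10), t, 128)
  expect_equal(z@A, 0)
  expect_equal(z@R2, 1)

  expect_error(fitSine(c(1, 2), t[1:2], 128), "3 phases")
})

test_that("flipping the sign reference shifts phi by half a cycle only", {
  t <- (0:9) / 10 * 1000 / 128
  D <- 1.4 * sin(2 * pi * (128 * t / 1000 + 0.6))
  f1 <- fitSine(D, t, 128)
  f2 <- fitSine(-D, t, 128)
  expect_equal(f1@A, f2@A, tolerance = 1e-12)
  expect_equal(f1@R2, f2@R2, tolerance = 1e-12)
  expect_equal((f2@phi - f1@phi) %% 1, 0.5, tolerance = 1e-9)
})

test_that("fitted amplitude is unbiased under noise (Monte Carlo)", {
  set.seed(77)
  t <- (0:9) / 10 * 1000 / 128
  A <- 3
  errs <- replicate(500, {
    D <- A * sin(2 * pi * (128 * t / 1000 + 0.1)) + stats::rnorm(10, 0, 0.1 * A)
    abs(fitSine(D, t, 128)@A - A)
  })
  expect_lt(mean(errs), 0.05 * A)
})

test_that("a figure-8 trace lowers the sine-fit R2 below the collinear case", {
  n <- 20
  u <- 2 * pi * (0:(n - 1)) / n
  t <- u / (2 * pi) * 1000 / 128
  pure <- cbind(2 * sin(u), 0, 0)
  fig8 <- cbind(2 * sin(u), 1.2 * sin(2 * u), 0)   # secondary lobe, doubled f
  fPure <- fitSine(signedNorms(pure), t, 128)
  f8 <- fitSine(signedNorms(fig8), t, 128)
  expect_gt(fPure@R2, 1 - 1e-9)
  expect_lt(f8@R2, fPure@R2 - 0.01)
  expect_equal(f8@A, 2, tolerance = 0.25)          # primary direction dominates
})

test_that("amplitude ratios divide fitted amplitudes", {
  t <- (0:9) / 10 * 1000 / 128
  mk <- function(A) fitSine(A * sin(2 * pi * 128 * t / 1000), t, 128)
  expect_equal(amplitudeRatio(mk(1.8), mk(1.2)), 1.5, tolerance = 1e-9)
  expect_equal(amplitudeRatio(mk(1), mk(1)), 1, tolerance = 1e-12)
  expect_error(amplitudeRatio(mk(1), mk(0)), "zero")
})

test_that("amplitude is proportional to distance from the rotation axis", {
  mot <- .sinusoidMotion(angleAmp = 1.5, axis = c(0, 0, 1), amp = c(0, 0, 0),
                         origin = c(0, 0, 0))
  t <- mot@phaseTimes
  dists <- c(5, 10, 20, 30, 40)
  amps <- vapply(dists, function(d) {
    tr <- displacePoints(mot, roiPointSet("p", "oss", rbind(c(d, 0, 0))))
    fitSine(tr, f = 128)@A
  }, numeric(1))
  fit <- stats::lm(amps ~ dists)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("the noise-floor report reflects static and drifting regions", {
  mot <- .sinusoidMotion(amp = c(0, 0, 0))
  roi <- roiPointSet("ref", "oss", rbind(c(10, 10, 10)))
  nf <- noiseFloor(mot, roi)
  expect_true(nf@pass)
  expect_equal(nf@maxTranslation, 0)
  expect_equal(nf@maxAngle, 0)
  expect_equal(nf@maxDisplacement, 0)

  drift <- .sinusoidMotion(amp = c(1, 0, 0))     # 1 voxel = 2.75 um >> 0.2
  nf2 <- noiseFloor(drift, roi)
  expect_false(nf2@pass)
  expect_true("translation_um" %in% nf2@failed)
})
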