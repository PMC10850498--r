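# Registration accuracy on phantoms with known ground truth. Crops here
# are kept small (21^3) so each case runs in seconds; the wider sweep over
# motion amplitudes lives in the acceptance suite.

test_that("cropping respects bounds and records its origin", {
  v <- array(stats::runif(16^3), c(16, 16, 16))
  whole <- cropSubvolume(v, subVolumeSpec("x", c(7, 7, 7), c(7, 7, 7)))
  expect_equal(dim(whole), c(15L, 15L, 15L))
  expect_equal(attr(whole, "origin"), c(0, 0, 0))

  unit <- cropSubvolume(v, subVolumeSpec("x", c(3, 4, 5), c(0, 0, 0)))
  expect_equal(dim(unit), c(1L, 1L, 1L))
  expect_equal(unit[1, 1, 1], v[4, 5, 6])

  expect_error(cropSubvolume(v, subVolumeSpec("x", c(2, 7, 7), c(7, 7, 7))),
               "exceeds the grid")
})

test_that("self-registration returns the identity", {
  ph <- generatePhaseVolumes(smallBodyPhantom(nPhases = 2L))
  v <- ph$series[[1]]
  tr <- registerSubvolume(v, v, smallBodySV(), fastRegParams())
  expect_lt(max(abs(tr@translation)), 1e-3)
  expect_lt(toAxisAngle(tr@rotation)@angle, 1e-3)
  expect_true(tr@converged)
})

test_that("a known sub-voxel translation is recovered", {
  amp <- c(1.25, -0.5, 0.75) / sin(2 * pi / 10)
  ph <- generatePhaseVolumes(smallBodyPhantom(translationAmplitude = amp))
  tru <- ph$truth@bodies$body$transforms[[2]]
  expect_equal(tru@translation, c(1.25, -0.5, 0.75), tolerance = 1e-9)
  tr <- registerSubvolume(ph$series[[1]], ph$series[[2]], smallBodySV(),
                          fastRegParams())
  expect_lt(max(abs(tr@translation - tru@translation)), 0.05)
  expect_lt(toAxisAngle(tr@rotation)@angle, 0.05)
})

test_that("a known rotation about the sub-volume centre is recovered", {
  ax <- c(1, 2, -1) / sqrt(6)
  ph <- generatePhaseVolumes(smallBodyPhantom(
    angleAmplitude = 1.5 / sin(2 * pi / 10), motionAxis = ax))
  tru <- toAxisAngle(ph$truth@bodies$body$transforms[[2]]@rotation)
  expect_equal(tru@angle, 1.5, tolerance = 1e-9)
  tr <- registerSubvolume(ph$series[[1]], ph$series[[2]], smallBodySV(),
                          fastRegParams())
  aa <- toAxisAngle(tr@rotation)
  expect_lt(abs(aa@angle - 1.5), 0.05)
  expect_lt(axisAngleBetween(aa@axis, ax), 2)
})

test_that("forward and backward registrations compose to the identity", {
  ph <- generatePhaseVolumes(smallBodyPhantom(
    angleAmplitude = 1, translationAmplitude = c(1, 0.5, -0.8),
    motionAxis = c(0, 1, 0)))
  sv <- smallBodySV()
  fw <- registerSubvolume(ph$series[[1]], ph$series[[2]], sv, fastRegParams())
  bw <- registerSubvolume(ph$series[[2]], ph$series[[1]], sv, fastRegParams())
  comp <- ossimotion:::.composeTransforms(bw, fw)
  expect_lt(max(abs(comp@translation)), 0.1)
  expect_lt(toAxisAngle(comp@rotation)@angle, 0.1)
})

test_that("the mutual-information metric also recovers known motion", {
  amp <- c(1.25, -0.5, 0.75) / sin(2 * pi / 10)
  ph <- generatePhaseVolumes(smallBodyPhantom(translationAmplitude = amp))
  tr <- registerSubvolume(ph$series[[1]], ph$series[[2]], smallBodySV(),
                          fastRegParams(metric = "mi"))
  expect_lt(max(abs(tr@translation - c(1.25, -0.5, 0.75))), 0.1)
})

test_that("constant-intensity crops are rejected", {
  v <- array(1, c(32, 32, 32))
  expect_error(registerSubvolume(v, v, subVolumeSpec("x", c(15, 15, 15),
                                                     c(8, 8, 8))),
               "constant")
})

test_that("registerPhaseSeries returns identity at phase 0 and one transform per phase", {
  ph <- generatePhaseVolumes(smallBodyPhantom(
    translationAmplitude = c(1, 0, 0), nPhases = 3L))
  out <- registerPhaseSeries(ph$series, list(smallBodySV()), fastRegParams())
  expect_length(out, 1L)
  expect_length(out[[1]], 3L)
  expect_equal(out[[1]][[1]]@rotation, diag(3))
  expect_equal(out[[1]][[1]]@translation, c(0, 0, 0))
  expect_identical(out[[1]][[2]]@phase, 1L)
  expect_identical(out[[1]][[3]]@phase, 2L)
})
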