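test_that("the outlier rules discard divergent estimates and only those", {
  keep <- rejectOutliers(c(1.0, 1.1, 0.9, 1.05, 5.5))
  expect_identical(as.logical(keep), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(attr(keep, "warning"))

  # identical values: zero dispersion passes everyone
  keep <- rejectOutliers(rep(2.5, 6))
  expect_true(all(keep))

  # two rows only: dispersion is meaningless, pass-all with warning
  keep <- rejectOutliers(cbind(c(1, 100), c(2, 2)),
                         outlierPolicy(minSurvivors = 2L))
  expect_true(all(keep))
  expect_true(attr(keep, "warning"))

  # a row is dropped when ANY of its parameters violates a rule
  m <- cbind(a = c(1, 1.02, 0.98, 1.01, 1.0), b = c(0.5, 0.5, 0.5, 0.5, 9))
  keep <- rejectOutliers(m)
  expect_identical(as.logical(keep), c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("transform averaging is component-wise with axis sign alignment", {
  tr <- rigidTransform(fromAxisAngle(c(0, 0, 1), 30), c(1, 2, 3), c(5, 5, 5))
  avg <- averageTransforms(list(tr))
  expect_equal(avg$transform@rotation, tr@rotation, tolerance = 1e-12)
  expect_equal(avg$transform@translation, tr@translation)
  expect_equal(unname(avg$dispersion), rep(0, 7))

  # axes a and -a with equal angles: sign alignment keeps the mean axis a
  a <- c(0, 1, 0)
  t1 <- rigidTransform(fromAxisAngle(a, 10), c(0, 0, 0), c(0, 0, 0))
  t2 <- rigidTransform(fromAxisAngle(-a, 10), c(0, 0, 0), c(0, 0, 0))
  avg <- averageTransforms(list(t1, t2))
  expect_equal(avg$axisAngle@axis, a, tolerance = 1e-12)
  expect_equal(avg$axisAngle@angle, 10, tolerance = 1e-12)

  expect_error(averageTransforms(list()), "empty")
  expect_error(averageTransforms(list(t1, rigidTransform(diag(3), c(0, 0, 0),
                                                         c(1, 0, 0)))),
               "origin")
})

test_that("averaging noisy estimates beats the typical individual estimate", {
  set.seed(21)
  truth <- rigidTransform(fromAxisAngle(c(1, 1, 0) / sqrt(2), 1.2),
                          c(0.8, -0.3, 0.5), c(0, 0, 0))
  x <- c(25, -10, 15)
  target <- applyTransform(truth, x)
  errs <- replicate(20, {
    noisy <- lapply(1:8, function(i) {
      daxis <- stats::rnorm(3, 0, 0.02)
      aa <- toAxisAngle(truth@rotation)
      rigidTransform(fromAxisAngle(aa@axis + daxis,
                                   aa@angle * (1 + stats::rnorm(1, 0, 0.05))),
                     truth@translation + stats::rnorm(3, 0, 0.05), c(0, 0, 0))
    })
    avg <- averageTransforms(noisy)
    indiv <- vapply(noisy, function(tr)
      sqrt(sum((applyTransform(tr, x) - target)^2)), numeric(1))
    c(mean = sqrt(sum((applyTransform(avg$transform, x) - target)^2)),
      med = stats::median(indiv))
  })
  expect_lt(mean(errs["mean", ]), mean(errs["med", ]))
})

test_that("the principal axis is the angle-weighted sign-aligned mean", {
  u <- c(1, 2, 2) / 3
  aas <- lapply(c(0.5, 1.5, 1.0), function(a)
    new("AxisAngle", axis = u, angle = a, degenerate = FALSE))
  expect_equal(principalRotationAxis(aas), u, tolerance = 1e-12)

  # alternating u and -u across half-cycles
  aas <- lapply(1:6, function(i)
    new("AxisAngle", axis = u * (-1)^i, angle = 1, degenerate = FALSE))
  expect_equal(abs(sum(principalRotationAxis(aas) * u)), 1, tolerance = 1e-12)

  degen <- list(new("AxisAngle", axis = c(0, 0, 1), angle = 0,
                    degenerate = TRUE))
  expect_error(principalRotationAxis(degen), "degenerate")
})

test_that("origin independence: any sub-volume's transform induces the same displacement", {
  set.seed(5)
  for (i in 1:25) {
    truth <- randomRigid(maxAngle = 3, maxT = 3, origin = stats::runif(3, 0, 100))
    svOrigins <- lapply(1:4, function(k) stats::runif(3, 0, 100))
    locals <- lapply(svOrigins, function(O) reexpressTransform(truth, O))
    x <- stats::runif(3, 0, 100)
    disp <- vapply(locals, function(tr) applyTransform(tr, x) - x,
                   numeric(3))
    expect_lt(max(abs(disp - disp[, 1])), 1e-9)
  }
})

test_that("ossicleMotion recovers a prescribed sinusoidal rotation profile", {
  set.seed(31)
  axis <- c(0, 1, 0)
  n <- 10
  angles <- 1.5 * sin(2 * pi * (0:9) / n)
  centers <- list(c(30, 30, 30), c(40, 30, 30), c(30, 40, 30), c(40, 40, 30))
  svT <- lapply(centers, function(O)
    lapply(1:n, function(j) {
      da <- if (j == 1) 0 else stats::rnorm(1, 0, 0.01)
      tr <- rigidTransform(fromAxisAngle(axis, angles[j] + da),
                           c(0.5, 0, 0.2) * sin(2 * pi * (j - 1) / n) +
                             if (j == 1) 0 else stats::rnorm(3, 0, 0.01),
                           c(35, 35, 30), phase = as.integer(j - 1))
      reexpressTransform(tr, O)
    }))
  mot <- ossicleMotion(svT, label = "oss", voxelSize = 2.75)
  expect_identical(nPhases(mot), 10L)
  expect_equal(mot@origin, centers[[1]])
  expect_lt(axisAngleBetween(mot@principalAxis, axis), 2)
  sa <- signedAngles(mot)
  ft <- fitSine(sa, mot@phaseTimes, 128)
  expect_gt(ft@R2, 0.99)
  expect_equal(ft@A, 1.5, tolerance = 0.05)
  # nothing discarded when all sub-volumes agree to within numeric noise
  expect_gt(mean(mot@survivors), 0.85)
})

test_that("whole_sv scope discards a consistently bad sub-volume everywhere", {
  n <- 5
  mk <- function(bad) lapply(1:n, function(j) {
    t <- c(sin(2 * pi * (j - 1) / n), 0, 0)
    if (bad && j > 1) t <- t + c(50, 0, 0)     # non-convergent garbage
    rigidTransform(diag(3), t, c(0, 0, 0), phase = as.integer(j - 1))
  })
  svT <- list(mk(FALSE), mk(FALSE), mk(FALSE), mk(TRUE))
  mot <- ossicleMotion(svT, scope = "whole_sv")
  expect_true(all(!mot@survivors[, 4]))
  expect_true(all(mot@survivors[, 1:3]))
  mot2 <- ossicleMotion(svT, scope = "per_phase")
  expect_true(all(!mot2@survivors[2:n, 4]))
})
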