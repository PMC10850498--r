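# Exact-arithmetic oracle for the commensurate 2 kHz / 128 Hz / 10-bin
# case: frame i at t = i/2 ms advances 8i/125 cycles, so the phase index is
# floor((80 i mod 1250) / 125), computable in integers.
.exactCommensuratePhase <- function(i) as.integer(((80 * i) %% 1250) %/% 125)

test_that("ascending zero crossings are detected with sub-sample precision", {
  t <- seq(0, 20, by = 0.01)                      # 100 kHz sampling, ms
  expect_lt(abs(detectZeroCrossing(t, sin(2 * pi * 128 * t / 1000))), 0.005)
  tref <- detectZeroCrossing(t, sin(2 * pi * 128 * (t - 1) / 1000))
  expect_lt(abs(tref - 1), 0.005)
  expect_error(detectZeroCrossing(t, rep(1, length(t))), "zero crossing")
  # descending-only start still finds the later ascending crossing
  tref <- detectZeroCrossing(t, cos(2 * pi * 64 * t / 1000))
  expect_lt(abs(tref - 1000 / 64 * 0.75), 0.005)
})

test_that("phase assignment follows the windowing rule", {
  g <- gatingSignal(128, tRef = 0)
  period <- 1000 / 128
  for (tv in list(c(0, 0L), c(0.39 * period, 3L),
                  c(2 * period + 0.39 * period, 3L),
                  c(-0.61 * period, 3L))) {
    a <- assignPhases(frameClock(tv[1], 1, 1), g, 10)
    expect_identical(a@phase, as.integer(tv[2]))
  }
})

test_that("commensurate 2 kHz / 128 Hz assignment matches the exact oracle", {
  tm <- generateTiming(40000, exposurePeriod = 0.5, fStim = 128)
  a <- assignPhases(tm$clock, tm$gating, 10)
  expect_identical(a@phase, vapply(0:39999, .exactCommensuratePhase,
                                   integer(1)))
  counts <- binStatistics(a)$counts
  expect_identical(counts, rep(c(4160L, 3840L), 5))
  expect_equal(binStatistics(a)$meanCount, 4000)
})

test_that("assignment is a partition for arbitrary clock/gating pairs", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(500:2000, 1)
    tm <- generateTiming(n, exposurePeriod = stats::runif(1, 0.1, 2),
                         exposureTime = 0.05,
                         fStim = stats::runif(1, 20, 500),
                         t0 = stats::runif(1, -10, 10),
                         jitterSd = 0.01, seed = i)
    nb <- sample(2:16, 1)
    a <- assignPhases(tm$clock, tm$gating, nb)
    counts <- binStatistics(a)$counts
    expect_identical(sum(counts), n)
    expect_true(all(a@phase >= 0L & a@phase < nb))
  }
})

test_that("shifting timestamps by whole stimulation periods changes nothing", {
  tm <- generateTiming(777, exposurePeriod = 0.37, exposureTime = 0.3,
                       fStim = 91)
  a1 <- assignPhases(tm$clock, tm$gating, 10)
  period <- 1000 / 91
  shifted <- frameClock(tm$clock@timestamps + 13 * period, 0.37, 0.3)
  a2 <- assignPhases(shifted, tm$gating, 10)
  expect_identical(a1@phase, a2@phase)
})

test_that("bin statistics report occupancy and angular coverage", {
  g <- gatingSignal(128)
  a <- assignPhases(frameClock(3.3, 1, 1), g, 10)
  counts <- binStatistics(a)$counts
  expect_identical(sum(counts == 1L), 1L)
  expect_identical(sum(counts), 1L)

  # uniform 360-degree rotation over the commensurate scan: every phase
  # covers the full turn; exact enumeration of the 125-frame supercycle
  # puts the largest within-phase angular gap at 0.144 degrees
  tm <- generateTiming(40000, exposurePeriod = 0.5, fStim = 128)
  ang <- (0:39999) * 360 / 40000
  a <- assignPhases(tm$clock, tm$gating, 10, angles = ang)
  st <- binStatistics(a)
  expect_true(all(st$angularSpan > 359.8))
  expect_true(all(st$maxAngularGap <= 0.144 + 1e-9))
})

test_that("flat/dark correction is exact and flags zero denominators", {
  dark <- matrix(10, 4, 4)
  flat <- matrix(30, 4, 4)
  expect_equal(unclass(flatdarkCorrect(flat, dark, flat))[1:16],
               rep(1, 16))
  expect_equal(unclass(flatdarkCorrect(dark, dark, flat))[1:16],
               rep(0, 16))
  mid <- dark + 0.5 * (flat - dark)
  expect_equal(unclass(flatdarkCorrect(mid, dark, flat))[1:16],
               rep(0.5, 16))

  flat2 <- flat; flat2[2, 2] <- 10           # one dead denominator pixel
  cor <- flatdarkCorrect(mid, dark, flat2)
  expect_equal(cor[2, 2], 0)
  expect_identical(attr(cor, "nZeroDenominator"), 1L)
  expect_error(flatdarkCorrect(mid, dark, dark), "vanishes")
})

test_that("phase grid arithmetic matches the stimulation period", {
  pg <- phaseGrid(128, 10)
  expect_equal(pg@period, 7.8125)
  expect_equal(pg@binWidth, 0.78125)
  expect_equal(pg@binStartTimes[1], 0)
  expect_equal(length(pg@binCenterTimes), 10L)
  expect_equal(pg@binWidth * nPhases(pg), pg@period, tolerance = 1e-12)
})
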