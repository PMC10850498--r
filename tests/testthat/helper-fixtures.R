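# Shared fixtures: small phantoms sized for fast unit tests, and a few
# random-object generators under fixed seeds.

# Single textured body on a 64^3 grid; amplitudes chosen by the caller.
smallBodyPhantom <- function(angleAmplitude = 0,
                             translationAmplitude = c(0, 0, 0),
                             motionAxis = c(0, 0, 1), nPhases = 10L,
                             noiseSigma = 0, shape = "capsule",
                             seed = 3L, textureSeed = 11L) {
  phantomSpec(c(64, 64, 64), list(
    bodySpec("body", shape, center = c(32, 32, 32), size = c(20, 20, 21),
             textureSeed = textureSeed, motionAxis = motionAxis,
             angleAmplitude = angleAmplitude,
             translationAmplitude = translationAmplitude,
             textureContrast = 0.4)),
    nPhases = nPhases, noiseSigma = noiseSigma, seed = seed)
}

smallBodySV <- function(halfExtents = c(10, 10, 10))
  subVolumeSpec("body", c(32, 32, 32), halfExtents)

# Random proper rotation from a uniform axis and a given angle range (deg).
randomRotation <- function(maxAngle = 179) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  fromAxisAngle(ax, stats::runif(1, 0, maxAngle))
}

randomRigid <- function(maxAngle = 179, maxT = 5, origin = stats::runif(3, 0, 100))
  rigidTransform(randomRotation(maxAngle), stats::runif(3, -maxT, maxT),
                 origin)

# Fast registration parameters for small unit-test crops.
fastRegParams <- function(...) registrationParams(pyramidLevels = 2L, ...)
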