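# Retrospective phase gating: sort projection frames into phase windows of
# the stimulation cycle using the gating sine and the camera exposure clock.

#' Detect the first ascending zero crossing of a sampled gating trace
#'
#' Scans the trace for the first sign change from non-positive to positive
#' and linearly interpolates the crossing time between the two samples.
#'
#' @param times sample times, ms.
#' @param values sampled gating-signal values.
#' @return Crossing time `tRef` in ms.
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' detectZeroCrossing(t, sin(2 * pi * 128 * (t - 1) / 1000))
#' @export
detectZeroCrossing <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  below <- values <= 0
  asc <- which(below[-length(values)] & values[-1] > 0)
  if (!length(asc)) stop("no ascending zero crossing found in the trace")
  i <- asc[1L]
  if (values[i] == 0) return(times[i])
  # linear interpolation between samples i and i+1
  times[i] + (0 - values[i]) / (values[i + 1] - values[i]) *
    (times[i + 1] - times[i])
}

# Guard against double-rounding at exact bin edges: attainable fractional
# positions are far coarser than 1e-9 of a bin, so nudging up recovers
# exact-arithmetic binning for commensurate clock/stimulation pairs.
.bin_eps <- 1e-9

#' Assign projection frames to motion phases
#'
#' Frame i with exposure-start time t_i lands in phase
#' `floor(frac((t_i - tRef) * f) * nPhases)`: phase 0 begins at the
#' ascending zero crossing of the gating sine. Times before `tRef` wrap via
#' the mathematical fractional part into [0, 1), so no frame is dropped.
#'
#' @param clock a [FrameClock-class].
#' @param gating a [GatingSignal-class].
#' @param nPhases number of phase windows (default 10).
#' @param angles optional per-frame projection angles (degrees) to carry
#'   through to [binStatistics()].
#' @return A [PhaseAssignment-class]: a partition of all frames.
#' @export
assignPhases <- function(clock, gating, nPhases = 10L, angles = numeric(0)) {
  stopifnot(is(clock, "FrameClock"), is(gating, "GatingSignal"))
  nPhases <- as.integer(nPhases)
  if (nPhases < 2L) stop("nPhases must be >= 2")
  cycles <- (clock@timestamps - gating@tRef) * gating@fStim / 1000
  fr <- cycles - floor(cycles)
  idx <- as.integer(floor(fr * nPhases + .bin_eps)) %% nPhases
  new("PhaseAssignment", phase = idx, nPhases = nPhases,
      angles = as.numeric(angles))
}

#' Per-phase occupancy and angular-coverage statistics
#'
#' @param assignment a [PhaseAssignment-class].
#' @return A list with `counts` (per-phase frame counts, summing to the
#'   number of frames), `meanCount`, `frames` (per-phase 0-based frame-index
#'   lists) and, when projection angles are attached, `angularSpan` and
#'   `maxAngularGap` per phase (degrees, treating angles modulo 360).
#' @export
binStatistics <- function(assignment) {
  stopifnot(is(assignment, "PhaseAssignment"))
  n <- assignment@nPhases
  counts <- tabulate(assignment@phase + 1L, n)
  frames <- split(seq_along(assignment@phase) - 1L,
                  factor(assignment@phase, levels = 0:(n - 1L)))
  out <- list(counts = counts, meanCount = mean(counts), frames = frames)
  if (length(assignment@angles)) {
    ang <- assignment@angles %% 360
    gaps <- spans <- numeric(n)
    for (p in seq_len(n)) {
      a <- sort(ang[assignment@phase == p - 1L])
      if (length(a) < 2L) {
        gaps[p] <- 360; spans[p] <- 0
      } else {
        d <- c(diff(a), a[1] + 360 - a[length(a)])
        gaps[p] <- max(d)
        spans[p] <- 360 - max(d)
      }
    }
    out$maxAngularGap <- gaps
    out$angularSpan <- spans
  }
  out
}

#' Check the motion-blur exposure constraint
#'
#' The effective exposure must not exceed one phase window (one tenth of
#' the stimulation period for 10 phases), or the frame blurs across
#' phases.
#'
#' @param clock a [FrameClock-class].
#' @param gating a [GatingSignal-class].
#' @param nPhases number of phase windows (default 10).
#' @return Logical: exposure time within one phase window.
#' @examples
#' tm <- generateTiming(10, exposureTime = 0.495)
#' exposureWithinPhaseWindow(tm$clock, tm$gating)
#' @export
exposureWithinPhaseWindow <- function(clock, gating, nPhases = 10L) {
  stopifnot(is(clock, "FrameClock"), is(gating, "GatingSignal"))
  clock@exposureTime <= phaseGrid(gating@fStim, nPhases)@binWidth
}

#' Dark- and flat-field correct a projection
#'
#' `corrected = (projection - dark) / (flat - dark)`. Pixels where the
#' denominator vanishes are set to 0 and counted; an all-zero denominator is
#' rejected.
#'
#' @param projection,dark,flat numeric arrays of one shape.
#' @return Corrected array with attribute `nZeroDenominator`.
#' @export
flatdarkCorrect <- function(projection, dark, flat) {
  stopifnot(identical(dim(projection), dim(dark)),
            identical(dim(projection), dim(flat)))
  den <- flat - dark
  bad <- den == 0
  if (all(bad)) stop("flat - dark vanishes everywhere; cannot correct")
  out <- (projection - dark) / den
  out[bad] <- 0
  attr(out, "nZeroDenominator") <- sum(bad)
  out
}
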