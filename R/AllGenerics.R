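#' @import methods
NULL

#' Number of motion phases
#'
#' @param x a [PhaseSeries-class], [PhaseAssignment-class] or
#'   [OssicleMotion-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' Physical voxel size in micrometres
#'
#' @param x an object carrying a voxel size.
#' @return Numeric scalar (um).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Rotation matrix of a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return 3x3 orthonormal matrix.
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' Translation vector of a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return Numeric 3-vector in voxel units.
#' @export
setGeneric("translationVector", function(x) standardGeneric("translationVector"))

#' Rotation-centre origin of a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return Numeric 3-vector, absolute 0-based voxel coordinates.
#' @export
setGeneric("transformOrigin", function(x) standardGeneric("transformOrigin"))

#' Phase bin times
#'
#' @param x a [PhaseSeries-class].
#' @return Numeric vector of times (ms) at which each phase volume is taken.
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))
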