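#' @name accessors
#' @title Accessors for wormPosture classes
#'
#' @description Slot accessors for [PostureRecording-class],
#' [EigenDecomposition-class] and [AmplitudeTrajectory-class] objects.
#' Use these instead of \code{@} slot access.
#'
#' @param object a wormPosture S4 object.
#' @return The requested component: metadata scalars, numeric vectors, or
#'   matrices as documented per class.
#' @aliases angles timestamps gait stage samplingRate recordingId nFrames
#'   nSegments eigenworms eigenvalues varianceFraction meanPosture amplitudes
NULL

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setGeneric("gait", function(object) standardGeneric("gait"))
#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("eigenworms", function(object) standardGeneric("eigenworms"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("varianceFraction",
           function(object) standardGeneric("varianceFraction"))
#' @rdname accessors
#' @export
setGeneric("meanPosture", function(object) standardGeneric("meanPosture"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
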