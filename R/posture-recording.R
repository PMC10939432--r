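#' Construct a PostureRecording
#'
#' User-facing constructor validating the invariants of the tracked-posture
#' format: one timestamp per frame, finite angles with \code{|angle| < pi},
#' strictly increasing time. If the median frame interval deviates by more
#' than 20\% from \code{1/samplingRate} a warning is raised (tracking gaps or
#' a wrong nominal rate), but the recording is kept.
#'
#' @param angles numeric \code{T x S} matrix of bending angles (radians).
#' @param timestamps numeric vector of length T, seconds, strictly
#'   increasing. Defaults to uniform sampling at \code{samplingRate}.
#' @param gait one of \code{"swimming"}, \code{"crawling"},
#'   \code{"transition"}, \code{"unknown"}.
#' @param stage developmental stage (\code{"youngL1"}, \code{"lateL1"},
#'   \code{"L2"}, \code{"L3"}, \code{"L4"}, \code{"adult"},
#'   \code{"unknown"}).
#' @param recordingId identifier string.
#' @param samplingRate nominal sampling rate in Hz (default 14, the tracker
#'   frame rate).
#' @return A [PostureRecording-class] object.
#' @examples
#' rec <- PostureRecording(matrix(rnorm(50, sd = 0.1), 5, 10))
#' nFrames(rec)
#' @export
PostureRecording <- function(angles, timestamps = NULL, gait = "unknown",
                             stage = "unknown", recordingId = "unnamed",
                             samplingRate = 14) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  if (is.null(timestamps))
    timestamps <- (seq_len(nrow(angles)) - 1) / samplingRate
  obj <- new("PostureRecording",
             recordingId = as.character(recordingId),
             gait = as.character(gait), stage = as.character(stage),
             timestamps = as.numeric(timestamps), angles = angles,
             samplingRate = as.numeric(samplingRate))
  .checkFrameInterval(obj)
  obj
}

.checkFrameInterval <- function(rec) {
  if (nFrames(rec) < 2L) return(invisible(NULL))
  med <- stats::median(diff(rec@timestamps))
  nominal <- 1 / rec@samplingRate
  if (abs(med - nominal) > 0.2 * nominal)
    warning(sprintf(
      "recording '%s': median frame interval %.4fs deviates >20%% from nominal %.4fs",
      rec@recordingId, med, nominal), call. = FALSE)
  invisible(NULL)
}

#' @rdname accessors
setMethod("angles", "PostureRecording", function(object) object@angles)
#' @rdname accessors
setMethod("timestamps", "PostureRecording", function(object) object@timestamps)
#' @rdname accessors
setMethod("gait", "PostureRecording", function(object) object@gait)
#' @rdname accessors
setMethod("stage", "PostureRecording", function(object) object@stage)
#' @rdname accessors
setMethod("samplingRate", "PostureRecording",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("recordingId", "PostureRecording", function(object) object@recordingId)
#' @rdname accessors
setMethod("nFrames", "PostureRecording", function(object) nrow(object@angles))
#' @rdname accessors
setMethod("nSegments", "PostureRecording", function(object) ncol(object@angles))

setMethod("show", "PostureRecording", function(object) {
  cat(sprintf("PostureRecording '%s'\n", object@recordingId))
  cat(sprintf("  gait: %s  stage: %s\n", object@gait, object@stage))
  cat(sprintf("  %d frames x %d segment angles, %.5g Hz (%.2f s)\n",
              nFrames(object), nSegments(object), object@samplingRate,
              diff(range(object@timestamps))))
})

#' @rdname accessors
setMethod("eigenworms", "EigenDecomposition", function(object) object@eigenworms)
#' @rdname accessors
setMethod("eigenvalues", "EigenDecomposition", function(object) object@eigenvalues)
#' @rdname accessors
setMethod("varianceFraction", "EigenDecomposition",
          function(object) object@varianceFraction)
#' @rdname accessors
setMethod("meanPosture", "EigenDecomposition", function(object) object@meanPosture)

setMethod("show", "EigenDecomposition", function(object) {
  S <- length(object@meanPosture)
  cat(sprintf("EigenDecomposition over %d segment angles (%s)\n", S,
              object@source))
  k <- min(4L, S)
  cat(sprintf("  leading variance fractions: %s\n",
              paste(sprintf("%.3f", object@varianceFraction[seq_len(k)]),
                    collapse = " ")))
})

#' @rdname accessors
setMethod("amplitudes", "AmplitudeTrajectory", function(object) object@amplitudes)
#' @rdname accessors
setMethod("samplingRate", "AmplitudeTrajectory",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("nFrames", "AmplitudeTrajectory", function(object) nrow(object@amplitudes))

setMethod("show", "AmplitudeTrajectory", function(object) {
  cat(sprintf("AmplitudeTrajectory: %d frames x %d eigenworms, %.5g Hz (basis %s)\n",
              nrow(object@amplitudes), ncol(object@amplitudes),
              object@samplingRate, object@basisId))
})

setMethod("show", "PhaseSpeedProfile", function(object) {
  filled <- object@binCounts > 0L
  cat(sprintf("PhaseSpeedProfile: %d bins, %d frames", object@nBins,
              sum(object@binCounts)))
  if (any(filled))
    cat(sprintf(", mean speed %.3g [%.3g, %.3g]",
                mean(object@meanSpeed[filled]),
                min(object@meanSpeed[filled]),
                max(object@meanSpeed[filled])))
  cat("\n")
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d, mass %.4f\n", length(object@x),
              length(object@y), densityMass(object)))
})
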