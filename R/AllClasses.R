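#' @import methods
NULL

.GAITS <- c("swimming", "crawling", "transition", "unknown")
.STAGES <- c("youngL1", "lateL1", "L2", "L3", "L4", "adult", "unknown")

#' PostureRecording: one tracked locomotion session
#'
#' Container for a single tracked recording of worm posture: a vector of
#' timestamps (seconds) and a \code{T x S} matrix of inter-segment bending
#' angles (radians), together with gait and developmental-stage metadata.
#' The tracking convention divides the body into \code{S + 1} segments along
#' the anterior-posterior axis, yielding \code{S} angles per frame
#' (default \code{S = 10}, sampled at 14 Hz).
#'
#' @slot recordingId character scalar identifying the session.
#' @slot gait one of \code{"swimming"}, \code{"crawling"},
#'   \code{"transition"}, \code{"unknown"}.
#' @slot stage one of \code{"youngL1"}, \code{"lateL1"}, \code{"L2"},
#'   \code{"L3"}, \code{"L4"}, \code{"adult"}, \code{"unknown"}.
#' @slot timestamps numeric vector of strictly increasing times in seconds.
#' @slot angles numeric \code{T x S} matrix of signed bending angles in
#'   radians (dorsal-to-ventral sign convention as exported by the tracker).
#' @slot samplingRate nominal sampling rate in Hz.
#'
#' @seealso [PostureRecording()] for the user-facing constructor,
#'   [readRecording()] to parse the 11-column text format.
#' @exportClass PostureRecording
setClass("PostureRecording",
  representation(
    recordingId  = "character",
    gait         = "character",
    stage        = "character",
    timestamps   = "numeric",
    angles       = "matrix",
    samplingRate = "numeric"
  ),
  prototype(
    recordingId = "unnamed", gait = "unknown", stage = "unknown",
    samplingRate = 14
  )
)

setValidity("PostureRecording", function(object) {
  msg <- character()
  if (length(object@recordingId) != 1L)
    msg <- c(msg, "recordingId must be a single string")
  if (!object@gait %in% .GAITS)
    msg <- c(msg, sprintf("gait must be one of: %s", paste(.GAITS, collapse = ", ")))
  if (!object@stage %in% .STAGES)
    msg <- c(msg, sprintf("stage must be one of: %s", paste(.STAGES, collapse = ", ")))
  if (nrow(object@angles) < 1L)
    msg <- c(msg, "recording must contain at least one frame")
  if (nrow(object@angles) != length(object@timestamps))
    msg <- c(msg, "angles row count must equal timestamps length")
  if (any(!is.finite(object@angles)))
    msg <- c(msg, "all angles must be finite after cleaning")
  else if (any(abs(object@angles) >= pi))
    msg <- c(msg, "segment angles must satisfy |angle| < pi radians")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive number")
  if (length(msg)) msg else TRUE
})

#' EigenDecomposition: an eigenworm basis
#'
#' Result of eigendecomposing a posture covariance matrix C(s, s'). The
#' columns of \code{eigenworms} are the orthonormal eigenvectors (canonical
#' body shapes, "eigenworms"), ordered by descending eigenvalue; the
#' eigenvalues are the posture variance captured by each mode.
#'
#' @slot meanPosture numeric length-S mean angle profile (radians).
#' @slot eigenworms numeric \code{S x S} matrix, one eigenworm per column.
#' @slot eigenvalues numeric length-S vector, descending, non-negative.
#' @slot varianceFraction eigenvalues normalised to sum to 1.
#' @slot source character description of the recordings pooled.
#'
#' @seealso [eigenDecompose()], [pooledMeanCovariance()],
#'   [projectAmplitudes()]
#' @exportClass EigenDecomposition
setClass("EigenDecomposition",
  representation(
    meanPosture      = "numeric",
    eigenworms       = "matrix",
    eigenvalues      = "numeric",
    varianceFraction = "numeric",
    source           = "character"
  )
)

setValidity("EigenDecomposition", function(object) {
  msg <- character()
  S <- length(object@meanPosture)
  if (!all(dim(object@eigenworms) == c(S, S)))
    msg <- c(msg, "eigenworms must be an S x S matrix")
  if (length(object@eigenvalues) != S || length(object@varianceFraction) != S)
    msg <- c(msg, "eigenvalues and varianceFraction must have length S")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted in descending order")
  if (any(object@eigenvalues < 0))
    msg <- c(msg, "eigenvalues must be non-negative")
  gram <- crossprod(object@eigenworms)
  if (max(abs(gram - diag(S))) > 1e-8)
    msg <- c(msg, "eigenworm columns must be orthonormal (tolerance 1e-8)")
  if (abs(sum(object@varianceFraction) - 1) > 1e-10)
    msg <- c(msg, "variance fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' AmplitudeTrajectory: eigenworm amplitudes over time
#'
#' The \code{T x K} matrix of projection coefficients of mean-subtracted
#' postures onto the first K eigenworms, at a known sampling rate. During
#' coordinated rhythmic locomotion the first two columns trace the
#' characteristic ring structure whose angular position encodes the phase of
#' the undulation cycle.
#'
#' @slot amplitudes numeric \code{T x K} matrix (radian-scaled projection
#'   coefficients).
#' @slot samplingRate sampling rate in Hz.
#' @slot basisId identifier of the [EigenDecomposition-class] basis used.
#' @exportClass AmplitudeTrajectory
setClass("AmplitudeTrajectory",
  representation(
    amplitudes   = "matrix",
    samplingRate = "numeric",
    basisId      = "character"
  )
)

setValidity("AmplitudeTrajectory", function(object) {
  msg <- character()
  if (any(!is.finite(object@amplitudes)))
    msg <- c(msg, "amplitudes must be finite")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive number")
  if (length(msg)) msg else TRUE
})

#' PhaseSpeedProfile: phase-binned speed around the locomotor cycle
#'
#' Mean trajectory speed in eigenworm space as a function of phase in the
#' ring, binned over \code{(-pi, pi]}. Bins that received no frames carry
#' \code{NA} in \code{meanSpeed}.
#'
#' @slot binCenters bin-center phases in radians, spanning \code{(-pi, pi]}.
#' @slot meanSpeed mean speed per bin (amplitude units per second); \code{NA}
#'   for empty bins.
#' @slot binCounts number of frames per bin.
#' @slot nBins number of phase bins.
#' @exportClass PhaseSpeedProfile
setClass("PhaseSpeedProfile",
  representation(
    binCenters = "numeric",
    meanSpeed  = "numeric",
    binCounts  = "integer",
    nBins      = "integer"
  )
)

setValidity("PhaseSpeedProfile", function(object) {
  msg <- character()
  n <- object@nBins
  if (length(object@binCenters) != n || length(object@meanSpeed) != n ||
      length(object@binCounts) != n)
    msg <- c(msg, "binCenters, meanSpeed, binCounts must all have length nBins")
  if (any(object@binCounts < 0))
    msg <- c(msg, "binCounts must be non-negative")
  filled <- object@binCounts > 0L
  if (any(is.na(object@meanSpeed[filled])) ||
      any(object@meanSpeed[filled] < 0))
    msg <- c(msg, "meanSpeed must be non-negative wherever binCounts > 0")
  if (any(!is.na(object@meanSpeed[!filled])))
    msg <- c(msg, "empty bins must carry NA meanSpeed")
  if (length(msg)) msg else TRUE
})

#' DensityGrid: 2D kernel density estimate of amplitude distributions
#'
#' A Gaussian kernel density estimate of the joint distribution of two
#' eigenworm amplitudes, evaluated on a regular grid. The bandwidth matrix is
#' the data covariance scaled by Scott's rule.
#'
#' @slot x,y grid coordinates in amplitude units.
#' @slot density non-negative matrix, \code{density[i, j]} evaluated at
#'   \code{(x[i], y[j])}.
#' @slot bandwidth the 2 x 2 kernel covariance matrix.
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(
    x         = "numeric",
    y         = "numeric",
    density   = "matrix",
    bandwidth = "matrix"
  )
)

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (!all(dim(object@density) == c(length(object@x), length(object@y))))
    msg <- c(msg, "density must be length(x) x length(y)")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative everywhere")
  if (!all(dim(object@bandwidth) == c(2L, 2L)))
    msg <- c(msg, "bandwidth must be a 2 x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' UndulationParams: parameters of the synthetic undulation generator
#'
#' Parameter set for [generateUndulation()]. The generator produces a
#' travelling dorsoventral bending wave with optional within-cycle speed
#' modulation, per-segment measurement noise, and intermittent coordination
#' lapses during which the wave collapses and independent segment noise takes
#' over (raising the dimensionality of the recording, as in young-L1 worms).
#'
#' @slot nSegments number of inter-segment angles (default 10).
#' @slot amplitude wave amplitude in radians.
#' @slot spatialWavelength wavelength of the body wave in body lengths
#'   (swimming-like ~2.0, crawling-like ~1.0).
#' @slot frequencyHz temporal undulation frequency in Hz.
#' @slot speedModulationDepth depth m in [0, 1) of the within-cycle angular
#'   speed modulation dphi/dt = 2*pi*f*(1 + m*cos(2*phi)).
#' @slot noiseSd per-segment Gaussian measurement noise, radians.
#' @slot lapseRate expected coordination lapses per second (Poisson onsets).
#' @slot lapseDurationS mean lapse duration, seconds (exponential).
#' @slot durationS recording duration, seconds.
#' @slot samplingRateHz sampling rate, Hz (default 14).
#' @slot seed integer RNG seed; identical seeds give identical recordings.
#' @seealso [undulationParams()], [generateUndulation()]
#' @exportClass UndulationParams
setClass("UndulationParams",
  representation(
    nSegments            = "integer",
    amplitude            = "numeric",
    spatialWavelength    = "numeric",
    frequencyHz          = "numeric",
    speedModulationDepth = "numeric",
    noiseSd              = "numeric",
    lapseRate            = "numeric",
    lapseDurationS       = "numeric",
    durationS            = "numeric",
    samplingRateHz       = "numeric",
    seed                 = "integer"
  )
)

setValidity("UndulationParams", function(object) {
  msg <- character()
  ok1 <- function(x) length(x) == 1L && is.finite(x)
  if (!ok1(object@nSegments) || object@nSegments < 2L)
    msg <- c(msg, "nSegments must be an integer >= 2")
  if (!ok1(object@amplitude) || object@amplitude <= 0)
    msg <- c(msg, "amplitude must be > 0")
  if (!ok1(object@spatialWavelength) || object@spatialWavelength <= 0)
    msg <- c(msg, "spatialWavelength must be > 0")
  if (!ok1(object@frequencyHz) || object@frequencyHz <= 0)
    msg <- c(msg, "frequencyHz must be > 0")
  if (!ok1(object@speedModulationDepth) || object@speedModulationDepth < 0 ||
      object@speedModulationDepth >= 1)
    msg <- c(msg, "speedModulationDepth must lie in [0, 1)")
  if (!ok1(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!ok1(object@lapseRate) || object@lapseRate < 0)
    msg <- c(msg, "lapseRate must be >= 0")
  if (!ok1(object@lapseDurationS) || object@lapseDurationS <= 0)
    msg <- c(msg, "lapseDurationS must be > 0")
  if (!ok1(object@durationS) || object@durationS <= 0)
    msg <- c(msg, "durationS must be > 0")
  if (!ok1(object@samplingRateHz) || object@samplingRateHz <= 0)
    msg <- c(msg, "samplingRateHz must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})
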