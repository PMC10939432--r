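#' Parameters for the synthetic undulation generator
#'
#' Builds a validated [UndulationParams-class]. Defaults describe a
#' swimming-like gait: long spatial wavelength (C/S shapes), 2 Hz
#' undulation, and within-cycle speed modulation that makes the locomotor
#' cycle dwell in the C-shape — use [crawlParams()] for the crawling-like
#' contrast (short wavelength, uniform cycle speed). Spatial wavelength is
#' given in body lengths and converted internally to a per-segment phase
#' offset of \code{2*pi / (nSegments * spatialWavelength)}.
#'
#' @param nSegments number of inter-segment angles (default 10).
#' @param amplitude wave amplitude, radians (default 0.6).
#' @param spatialWavelength body lengths per spatial period (default 2.0).
#' @param frequencyHz undulation frequency, Hz (default 2.0).
#' @param speedModulationDepth within-cycle modulation depth in [0, 1)
#'   (default 0.4): the cycle phase advances as
#'   \code{dphi/dt = 2*pi*f*(1 + m*cos(2*phi))}.
#' @param noiseSd per-segment measurement noise, radians (default 0.05).
#' @param lapseRate expected coordination lapses per second (default 0).
#' @param lapseDurationS mean lapse duration, seconds (default 0.5).
#' @param durationS recording duration, seconds (default 30).
#' @param samplingRateHz sampling rate, Hz (default 14).
#' @param seed RNG seed (default 1).
#' @return An [UndulationParams-class].
#' @export
undulationParams <- function(nSegments = 10, amplitude = 0.6,
                             spatialWavelength = 2.0, frequencyHz = 2.0,
                             speedModulationDepth = 0.4, noiseSd = 0.05,
                             lapseRate = 0, lapseDurationS = 0.5,
                             durationS = 30, samplingRateHz = 14, seed = 1) {
  new("UndulationParams",
      nSegments = as.integer(nSegments), amplitude = as.numeric(amplitude),
      spatialWavelength = as.numeric(spatialWavelength),
      frequencyHz = as.numeric(frequencyHz),
      speedModulationDepth = as.numeric(speedModulationDepth),
      noiseSd = as.numeric(noiseSd), lapseRate = as.numeric(lapseRate),
      lapseDurationS = as.numeric(lapseDurationS),
      durationS = as.numeric(durationS),
      samplingRateHz = as.numeric(samplingRateHz), seed = as.integer(seed))
}

#' Crawling-like generator parameters
#'
#' [undulationParams()] preset for the crawling contrast: spatial wavelength
#' 1 body length (sinusoid spanning the body), 0.5 Hz undulation, and no
#' within-cycle speed modulation (the crawling wave propagates at constant
#' speed along the ring).
#'
#' @param ... overrides passed to [undulationParams()].
#' @return An [UndulationParams-class].
#' @export
crawlParams <- function(...) {
  defaults <- list(spatialWavelength = 1.0, frequencyHz = 0.5,
                   speedModulationDepth = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(undulationParams, args)
}

# run body with a private RNG stream; global .Random.seed untouched
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic posture recording
#'
#' Simulates a travelling dorsoventral bending wave
#' \code{theta(s, t) = A * e(t) * sin(2*pi*s / (S * lambda) - phi(t)) + eps}
#' with segment index s = 1..S and wavelength lambda in body lengths. The
#' cycle phase integrates \code{dphi/dt = 2*pi*f*(1 + m*cos(2*phi))}, so a
#' nonzero modulation depth m makes the trajectory spend more time at two
#' opposite phases of the ring (the bimodal swimming profile); m = 0 gives
#' the uniform crawling cycle. Gaussian measurement noise of sd
#' \code{noiseSd} is added per segment and frame.
#'
#' Coordination lapses emulate the uncoordinated episodes of young-L1
#' locomotion: onsets follow a Poisson process at \code{lapseRate} per
#' second with exponentially distributed durations (mean
#' \code{lapseDurationS}). During a lapse the wave envelope e(t) relaxes
#' toward 0 with a 0.2 s time constant and the measurement noise is
#' replaced by independent segment noise of sd \code{3 * noiseSd}; after the
#' lapse the envelope recovers with the same time constant. Lapses inflate
#' both the participation ratio and the density at the ring center.
#'
#' Identical parameter sets (including \code{seed}) produce bit-identical
#' recordings; the global RNG state is left untouched.
#'
#' @param params an [UndulationParams-class].
#' @param gait,stage,recordingId metadata for the returned
#'   [PostureRecording-class]; gait defaults to swimming-like vs
#'   crawling-like based on the modulation depth being nonzero.
#' @return A [PostureRecording-class].
#' @examples
#' rec <- generateUndulation(undulationParams(durationS = 5, seed = 42))
#' rec
#' @export
generateUndulation <- function(params, gait = NULL, stage = "unknown",
                               recordingId = NULL) {
  stopifnot(is(params, "UndulationParams"))
  validObject(params)
  if (is.null(gait))
    gait <- if (params@speedModulationDepth > 0) "swimming" else "crawling"
  if (is.null(recordingId))
    recordingId <- sprintf("synthetic_seed%d", params@seed)
  fs <- params@samplingRateHz
  dt <- 1 / fs
  T <- max(1L, round(params@durationS * fs))
  S <- params@nSegments
  sIdx <- seq_len(S)
  spatialPhase <- 2 * pi * sIdx / (S * params@spatialWavelength)

  .withSeed(params@seed, {
    # lapse onset/offset intervals (drawn first: fixed consumption order)
    lapse <- rep(FALSE, T)
    if (params@lapseRate > 0) {
      tEnd <- params@durationS
      tCur <- 0
      repeat {
        tCur <- tCur + stats::rexp(1, rate = params@lapseRate)
        if (tCur >= tEnd) break
        dur <- stats::rexp(1, rate = 1 / params@lapseDurationS)
        i0 <- max(1L, floor(tCur * fs) + 1L)
        i1 <- min(T, ceiling((tCur + dur) * fs))
        if (i0 <= i1) lapse[i0:i1] <- TRUE
      }
    }
    noise <- matrix(stats::rnorm(T * S), T, S)

    # phase integration (Euler, 20 substeps per frame for accuracy)
    nsub <- 20L
    h <- dt / nsub
    phi <- numeric(T)
    p <- 0
    w0 <- 2 * pi * params@frequencyHz
    m <- params@speedModulationDepth
    for (t in seq_len(T)) {
      phi[t] <- p
      for (i in seq_len(nsub)) p <- p + h * w0 * (1 + m * cos(2 * p))
    }

    # envelope relaxation toward 0 in a lapse, 1 otherwise (tau = 0.2 s)
    alpha <- 1 - exp(-dt / 0.2)
    env <- numeric(T)
    e <- 1
    for (t in seq_len(T)) {
      target <- if (lapse[t]) 0 else 1
      e <- e + alpha * (target - e)
      env[t] <- e
    }

    sd <- ifelse(lapse, 3 * params@noiseSd, params@noiseSd)
    wave <- (env * sin(outer(-phi, spatialPhase, `+`))) * params@amplitude
    theta <- wave + noise * sd
    theta[theta >= pi] <- pi - 1e-9
    theta[theta <= -pi] <- -pi + 1e-9

    PostureRecording(theta, timestamps = (seq_len(T) - 1) * dt, gait = gait,
                     stage = stage, recordingId = recordingId,
                     samplingRate = fs)
  })
}

#' Generate a cohort of synthetic recordings organized by stage
#'
#' Writes \code{nPerStage} recordings per developmental stage into the
#' standard \code{root/gait/stage/*.txt} layout, with per-file seeds derived
#' deterministically from \code{baseSeed}, the stage index, and the
#' within-stage index — re-running with the same arguments yields
#' byte-identical files. A \code{manifest.csv} in \code{root} records the
#' true generating parameters of every file for parameter-recovery tests.
#'
#' @param stageProfiles named list mapping stage name to an
#'   [UndulationParams-class] (the per-file seed overrides the profile's).
#' @param nPerStage recordings per stage, >= 1.
#' @param baseSeed integer seed the per-file seeds derive from.
#' @param root output directory (created if needed).
#' @param gait gait label and folder name (default \code{"swimming"}).
#' @return Invisibly, the manifest data.frame.
#' @export
generateStageCohort <- function(stageProfiles, nPerStage, baseSeed, root,
                                gait = "swimming") {
  stopifnot(is.list(stageProfiles), length(stageProfiles) >= 1L,
            !is.null(names(stageProfiles)), nPerStage >= 1)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root))
    stop(sprintf("cannot create output directory %s", root), call. = FALSE)
  manifest <- list()
  for (si in seq_along(stageProfiles)) {
    stageName <- names(stageProfiles)[si]
    prof <- stageProfiles[[si]]
    stopifnot(is(prof, "UndulationParams"))
    stageDir <- file.path(root, gait, stageName)
    dir.create(stageDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nPerStage)) {
      seed <- ((abs(baseSeed) %% 1000003L) * 1009L + si * 131L + i) %%
        2147483647L
      p <- prof
      p@seed <- as.integer(seed)
      rec <- generateUndulation(p, gait = gait, stage = stageName,
                                recordingId = sprintf("%s_%03d", stageName, i))
      path <- file.path(stageDir, sprintf("%s_%03d.txt", stageName, i))
      writeRecording(rec, path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        path = path, gait = gait, stage = stageName, seed = seed,
        nSegments = p@nSegments, amplitude = p@amplitude,
        spatialWavelength = p@spatialWavelength,
        frequencyHz = p@frequencyHz,
        speedModulationDepth = p@speedModulationDepth, noiseSd = p@noiseSd,
        lapseRate = p@lapseRate, lapseDurationS = p@lapseDurationS,
        durationS = p@durationS, samplingRateHz = p@samplingRateHz,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
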