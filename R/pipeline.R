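#' Configuration of a full posture-dynamics analysis
#'
#' Plain list of settings consumed by [runFullAnalysis()]; all numeric
#' fields are validated against the ranges of the functions they feed.
#'
#' @param datasetRoot dataset directory in \code{gait/stage} layout.
#' @param outputDir directory for result tables and the run log.
#' @param gait \code{"swimming"}, \code{"crawling"} or \code{"both"}.
#' @param stages stages to include (default all recognized ones).
#' @param kEigenworms eigenworms kept for variance/similarity tables
#'   (default 4).
#' @param nPhaseBins phase bins for the speed profile (default 24).
#' @param alpha family-wise error rate before Bonferroni correction
#'   (default 0.05).
#' @param testVariant \code{"welch"} (default) or \code{"standard"}.
#' @param minFrames minimum usable recording length (default 28).
#' @param seed integer seed recorded with the run (the analysis path itself
#'   is deterministic).
#' @return A list with class \code{"wormPostureConfig"}.
#' @export
analysisConfig <- function(datasetRoot, outputDir,
                           gait = "both",
                           stages = setdiff(.STAGES, "unknown"),
                           kEigenworms = 4, nPhaseBins = 24, alpha = 0.05,
                           testVariant = "welch", minFrames = 28, seed = 1) {
  cfg <- list(datasetRoot = datasetRoot, outputDir = outputDir, gait = gait,
              stages = stages, kEigenworms = as.integer(kEigenworms),
              nPhaseBins = as.integer(nPhaseBins), alpha = as.numeric(alpha),
              testVariant = testVariant, minFrames = as.integer(minFrames),
              seed = as.integer(seed))
  .validateConfig(cfg)
  class(cfg) <- "wormPostureConfig"
  cfg
}

.validateConfig <- function(cfg) {
  if (!cfg$gait %in% c("swimming", "crawling", "both"))
    stop("gait must be 'swimming', 'crawling' or 'both'", call. = FALSE)
  if (!all(cfg$stages %in% .STAGES))
    stop("unrecognized stage in config", call. = FALSE)
  if (cfg$kEigenworms < 1) stop("kEigenworms must be >= 1", call. = FALSE)
  if (cfg$nPhaseBins < 4) stop("nPhaseBins must be >= 4", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!cfg$testVariant %in% c("welch", "standard"))
    stop("testVariant must be 'welch' or 'standard'", call. = FALSE)
  if (cfg$minFrames < 2) stop("minFrames must be >= 2", call. = FALSE)
  invisible(TRUE)
}

#' Write an analysis config as a flat key = value text file
#'
#' @param config a \code{wormPostureConfig} from [analysisConfig()].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @seealso [readAnalysisConfig()] — the two round-trip exactly.
#' @export
writeAnalysisConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an analysis config written by [writeAnalysisConfig()]
#'
#' @param path flat key = value file.
#' @return A \code{wormPostureConfig}.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  vals <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  get1 <- function(k, default = NULL) {
    if (is.null(vals[[k]])) default else vals[[k]]
  }
  analysisConfig(
    datasetRoot = get1("datasetRoot"),
    outputDir = get1("outputDir"),
    gait = get1("gait", "both"),
    stages = strsplit(get1("stages", paste(setdiff(.STAGES, "unknown"),
                                           collapse = ",")), ",")[[1]],
    kEigenworms = as.integer(get1("kEigenworms", 4)),
    nPhaseBins = as.integer(get1("nPhaseBins", 24)),
    alpha = as.numeric(get1("alpha", 0.05)),
    testVariant = get1("testVariant", "welch"),
    minFrames = as.integer(get1("minFrames", 28)),
    seed = as.integer(get1("seed", 1)))
}

.logLine <- function(con, fmt, ...) {
  line <- sprintf(fmt, ...)
  writeLines(line, con)
  message(line)
}

#' Run the full posture-dynamics analysis over a dataset directory
#'
#' Orchestrates the whole pipeline per gait: discovery and reading of
#' 11-column recordings, the pooled eigenworm basis across all included
#' stages, the cumulative-variance curve, per-recording participation ratios
#' with stage summaries and Bonferroni-corrected pairwise tests, the pooled
#' phase-resolved speed profile of the ring, per-stage 2D amplitude density
#' grids, and per-stage eigenworm bases compared to the pooled basis by
#' cosine similarity. All tables are written as CSV under
#' \code{config$outputDir/<gait>/}; a \code{run.log} records every excluded
#' recording and the thresholds in effect. Unreadable recordings are logged
#' and skipped, not fatal.
#'
#' @param config a \code{wormPostureConfig} from [analysisConfig()].
#' @return Invisibly, a nested list of all result tables, one element per
#'   gait analyzed.
#' @export
runFullAnalysis <- function(config) {
  .validateConfig(config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outputDir, "run.log")
  con <- file(logPath, open = "wt")
  on.exit(close(con))
  .logLine(con, "wormPosture analysis: root=%s gait=%s minFrames=%d alpha=%g variant=%s",
           config$datasetRoot, config$gait, config$minFrames, config$alpha,
           config$testVariant)

  desc <- discoverDataset(config$datasetRoot)
  gaits <- if (config$gait == "both") c("swimming", "crawling") else config$gait
  desc <- desc[desc$gait %in% gaits & desc$stage %in% config$stages, ,
               drop = FALSE]
  if (nrow(desc) == 0L)
    stop("no usable recordings for the requested gait/stages", call. = FALSE)

  results <- list()
  for (g in intersect(gaits, unique(desc$gait))) {
    sub <- desc[desc$gait == g, , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(sub))) {
      rec <- tryCatch(
        readRecording(sub$path[i], gait = sub$gait[i], stage = sub$stage[i]),
        error = function(e) {
          .logLine(con, "skipped %s: %s", sub$path[i], conditionMessage(e))
          NULL
        })
      if (is.null(rec)) next
      if (nFrames(rec) < config$minFrames) {
        .logLine(con, "excluded %s: %d frames < minimum %d", sub$path[i],
                 nFrames(rec), config$minFrames)
        next
      }
      recs[[length(recs) + 1L]] <- rec
    }
    if (length(recs) == 0L) {
      .logLine(con, "gait %s: no usable recordings", g)
      next
    }
    .logLine(con, "gait %s: %d usable recordings", g, length(recs))
    outDir <- file.path(config$outputDir, g)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    results[[g]] <- .analyzeGait(recs, g, config, outDir, con)
  }
  if (length(results) == 0L)
    stop("no gait produced any usable recordings", call. = FALSE)
  invisible(results)
}

.analyzeGait <- function(recs, g, config, outDir, con) {
  S <- nSegments(recs[[1]])
  k <- min(config$kEigenworms, S)

  # pooled basis across all stages of this gait
  mc <- pooledMeanCovariance(recs)
  basis <- eigenDecompose(mc$covariance, mean = mc$mean,
                          source = sprintf("pooled:%s", g))

  ewTab <- as.data.frame(eigenworms(basis))
  names(ewTab) <- sprintf("EW%d_radians", seq_len(S))
  ewTab <- cbind(data.frame(segment = seq_len(S)), ewTab)
  utils::write.csv(ewTab, file.path(outDir, "eigenworms.csv"),
                   row.names = FALSE)

  varTab <- data.frame(
    eigenworm = seq_len(S),
    eigenvalue_rad2 = eigenvalues(basis),
    variance_fraction = varianceFraction(basis),
    cumulative_variance = cumsum(varianceFraction(basis)))
  utils::write.csv(varTab, file.path(outDir, "variance.csv"),
                   row.names = FALSE)

  # per-recording PR, stage summaries, pairwise tests
  prtab <- withCallingHandlers(
    prTable(recs, minFrames = config$minFrames),
    message = function(m) {
      writeLines(trimws(conditionMessage(m)), con); invokeRestart("muffleMessage")
    })
  utils::write.csv(prtab, file.path(outDir, "pr.csv"), row.names = FALSE)
  sumTab <- stageSummary(prtab)
  utils::write.csv(sumTab, file.path(outDir, "pr_summary.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(sumTab)))
    .logLine(con, "gait %s stage %s: n=%d meanPR=%.3f IQR=[%.3f, %.3f]",
             g, sumTab$stage[i], sumTab$n[i], sumTab$meanPR[i],
             sumTab$q25[i], sumTab$q75[i])

  if (length(unique(prtab$stage)) >= 2L) {
    tests <- pairwiseStageTests(prtab, alpha = config$alpha,
                                variant = config$testVariant)
    .logLine(con, "gait %s: %d pairwise comparisons, adjusted alpha %.5f",
             g, attr(tests, "nComparisons"), attr(tests, "adjustedAlpha"))
  } else {
    warning(sprintf("gait %s: only one stage present, pairwise test table empty",
                    g), call. = FALSE)
    .logLine(con, "gait %s: only one stage, no pairwise tests", g)
    tests <- data.frame(stageA = character(), stageB = character(),
                        tStatistic = numeric(), pValue = numeric(),
                        testVariant = character(), significant = logical())
  }
  utils::write.csv(tests, file.path(outDir, "pairwise_tests.csv"),
                   row.names = FALSE)

  # ring dynamics: first two amplitudes on the pooled basis
  trajs <- lapply(recs, projectAmplitudes, basis = basis, k = 2)
  profile <- phaseSpeedProfile(trajs, nBins = config$nPhaseBins)
  profTab <- data.frame(phase_bin_center_rad = profile@binCenters,
                        mean_speed_per_s = profile@meanSpeed,
                        n_frames = profile@binCounts)
  utils::write.csv(profTab, file.path(outDir, "phase_speed.csv"),
                   row.names = FALSE)

  # per-stage amplitude density grids (long format)
  densities <- list()
  for (s in unique(prtab$stage)) {
    pts <- do.call(rbind, lapply(
      trajs[vapply(recs, stage, "") == s],
      function(tr) amplitudes(tr)[, 1:2, drop = FALSE]))
    dg <- tryCatch(amplitudeDensity(pts), error = function(e) {
      .logLine(con, "gait %s stage %s: density skipped (%s)", g, s,
               conditionMessage(e))
      NULL
    })
    if (is.null(dg)) next
    densities[[s]] <- dg
    long <- data.frame(a1 = rep(dg@x, times = length(dg@y)),
                       a2 = rep(dg@y, each = length(dg@x)),
                       density = as.vector(dg@density))
    utils::write.csv(long, file.path(outDir, sprintf("density_%s.csv", s)),
                     row.names = FALSE)
  }

  # per-stage bases vs the pooled basis, first k eigenworms
  simRows <- list()
  for (s in unique(prtab$stage)) {
    stageRecs <- recs[vapply(recs, stage, "") == s]
    if (sum(vapply(stageRecs, nFrames, 0L)) <= S) next
    mcS <- pooledMeanCovariance(stageRecs)
    basisS <- eigenDecompose(mcS$covariance, mean = mcS$mean,
                             source = sprintf("stage:%s:%s", g, s))
    sim <- basisSimilarity(basisS, basis, k = k)
    simRows[[s]] <- data.frame(stage = s,
                               eigenworm = seq_len(k),
                               cosine_similarity = sim,
                               stringsAsFactors = FALSE)
  }
  simTab <- do.call(rbind, simRows)
  rownames(simTab) <- NULL
  utils::write.csv(simTab, file.path(outDir, "basis_similarity.csv"),
                   row.names = FALSE)

  list(basis = basis, variance = varTab, prTable = prtab,
       stageSummary = sumTab, pairwiseTests = tests, phaseSpeed = profTab,
       densities = densities, basisSimilarity = simTab)
}
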