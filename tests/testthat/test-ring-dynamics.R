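selfEmbed <- function(rec, k = 2) {
  mc <- pooledMeanCovariance(rec)
  basis <- suppressMessages(eigenDecompose(mc$covariance, mean = mc$mean))
  projectAmplitudes(rec, basis, k = k)
}

test_that("trajectory speed is the frame-to-frame distance times the rate", {
  A <- matrix(c(0, 0, 0.3, 0.4, 0.3, 0.4), 3, 2, byrow = TRUE)
  tr <- new("AmplitudeTrajectory", amplitudes = A, samplingRate = 14,
            basisId = "test")
  expect_equal(trajectorySpeed(tr), c(0.5 * 14, 0))
  expect_equal(trajectorySpeed(matrix(1, 5, 2)), rep(0, 4))
  expect_error(trajectorySpeed(matrix(0, 1, 2)), "at least 2 frames")

  # circle of radius r at angular rate w: speeds approach r*w as step -> 0
  r <- 0.7; w <- 2 * pi * 0.5; fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  sp <- trajectorySpeed(r * cbind(cos(w * t), sin(w * t)), samplingRate = fs)
  expect_equal(mean(sp), r * w, tolerance = 1e-4)
})

test_that("analytic phase of a sinusoid advances at 2*pi*f", {
  fs <- 14; t <- seq(0, 10, by = 1 / fs)
  ph <- analyticPhase(cos(2 * pi * 1 * t))
  interior <- 15:(length(t) - 15)
  slopes <- diff(unwrapPhase(ph[interior])) * fs
  expect_equal(mean(slopes), 2 * pi, tolerance = 0.02 * 2 * pi)
  # quadrature: sin lags cos by pi/2, same slope
  phS <- analyticPhase(sin(2 * pi * 1 * t))
  d <- (phS - ph)[interior]
  d <- atan2(sin(d), cos(d))
  expect_equal(mean(d), -pi / 2, tolerance = 0.05)
  expect_error(analyticPhase(rep(1, 100)), "degenerate")
  expect_error(analyticPhase(1:5), "at least 8 frames")
})

test_that("phase-binned speed recovers a constructed modulation", {
  set.seed(31)
  phase <- runif(20000, -pi, pi)
  speed <- 1 + 0.5 * cos(2 * phase)
  prof <- phaseBinnedSpeed(phase, speed, nBins = 24)
  expect_s4_class(prof, "PhaseSpeedProfile")
  expect_equal(sum(prof@binCounts), 20000L)
  # extremes at the constructed phases, within one 15-degree bin
  centers <- prof@binCenters
  minima <- centers[order(prof@meanSpeed)[1:2]]
  maxima <- centers[order(-prof@meanSpeed)[1:2]]
  binW <- 2 * pi / 24
  expect_true(all(sapply(minima, function(m)
    min(abs(atan2(sin(m - c(-pi / 2, pi / 2)), cos(m - c(-pi / 2, pi / 2)))))
    <= binW)))
  expect_true(all(sapply(maxima, function(m)
    min(abs(atan2(sin(m - c(0, pi)), cos(m - c(0, pi))))) <= binW)))
  expect_error(phaseBinnedSpeed(1:3, 1:4, 8), "same length")
})

test_that("uniform speed over whole cycles gives a flat profile and empty bins are NA", {
  phase <- seq(-pi + 1e-6, pi, length.out = 4800)
  prof <- phaseBinnedSpeed(phase, rep(2, 4800), nBins = 24)
  expect_equal(prof@meanSpeed, rep(2, 24))
  # a bin with no frames carries NA, others are unaffected
  keep <- abs(phase) > 2 * pi / 24   # empty the bins straddling phase 0
  prof2 <- phaseBinnedSpeed(phase[keep], rep(2, sum(keep)), nBins = 24)
  expect_true(anyNA(prof2@meanSpeed))
  expect_equal(prof2@meanSpeed[!is.na(prof2@meanSpeed)],
               rep(2, sum(!is.na(prof2@meanSpeed))))
})

test_that("a noiseless travelling wave yields a near-constant ring radius and flat speed", {
  rec <- waveRecording(420)   # 30 s, 15 cycles at 0.5 Hz
  tr <- selfEmbed(rec)
  r <- sqrt(rowSums(amplitudes(tr)^2))
  trim <- 8:(length(r) - 8)
  expect_lt(sd(r[trim]) / mean(r[trim]), 0.05)
  prof <- phaseSpeedProfile(tr)
  ms <- prof@meanSpeed[prof@binCounts > 0]
  expect_lt((max(ms) - min(ms)) / mean(ms), 0.05)
})

test_that("kernel density estimate conserves mass and honours Scott's rule", {
  set.seed(17)
  n <- 64
  pts <- cbind(rnorm(n), rnorm(n, sd = 2))
  g <- amplitudeDensity(pts)
  # Scott linear factor n^(-1/6) = 0.5 at n = 64: kernel cov = cov / 4
  expect_equal(g@bandwidth, cov(pts) * 64^(-1 / 3))
  expect_equal(64^(-1 / 6), 0.5)
  expect_true(all(g@density >= 0))
  expect_gte(densityMass(g), 0.97)
  expect_lte(densityMass(g), 1.0)

  # tight cluster at (2, 0): mode lands within one grid cell of it
  cl <- cbind(rnorm(1000, 2, 0.01), rnorm(1000, 0, 0.01))
  gc <- amplitudeDensity(cl)
  peak <- which(gc@density == max(gc@density), arr.ind = TRUE)[1, ]
  # mode within one cluster standard deviation of the true center
  expect_lt(abs(gc@x[peak[1]] - 2), 0.01)
  expect_lt(abs(gc@y[peak[2]] - 0), 0.01)
  expect_error(amplitudeDensity(cbind(1:20, 2 * (1:20))), "singular")
})

test_that("ring occupancy separates clean rings from collapsed clouds", {
  th <- seq(0, 2 * pi, length.out = 100)
  ring <- cbind(cos(th), sin(th))
  expect_equal(ringOccupancy(ring, 0.5), 0)
  collapsed <- rbind(matrix(0, 99, 2), c(3, 0))
  expect_equal(ringOccupancy(collapsed, 0.5), 0.99)
  mix <- rbind(2 * ring, 0.05 * ring)
  expect_equal(ringOccupancy(mix, 0.5), 0.5)
  expect_error(ringOccupancy(matrix(0, 20, 2)), "degenerate")
  expect_error(ringOccupancy(ring, 1.5), "coreFraction")
})

test_that("coordination lapses raise center occupancy of the ring", {
  clean <- generateUndulation(undulationParams(durationS = 30, seed = 21))
  lapsing <- generateUndulation(undulationParams(durationS = 30, seed = 21,
                                                 lapseRate = 0.6))
  occClean <- ringOccupancy(selfEmbed(clean))
  occLapse <- ringOccupancy(selfEmbed(lapsing))
  expect_gt(occLapse, occClean)
})

test_that("a transition recording embeds as two concentric rings in distinct planes", {
  sw <- generateUndulation(undulationParams(noiseSd = 0.02, durationS = 30,
                                            seed = 5))
  cr <- generateUndulation(crawlParams(noiseSd = 0.02, durationS = 30,
                                       seed = 6))
  joint <- PostureRecording(rbind(angles(sw), angles(cr)),
                            gait = "transition", recordingId = "transition")
  emb <- transitionEmbedding(joint, k = 3)
  expect_equal(ncol(amplitudes(emb)), 3L)
  # the two gaits dominate the first four modes
  mc <- pooledMeanCovariance(joint)
  basis <- suppressMessages(eigenDecompose(mc$covariance))
  expect_gt(cumulativeVariance(basis, 4), 0.95)
  labels <- rep(c("swim", "crawl"), c(nFrames(sw), nFrames(cr)))
  sep <- ringSeparation(emb, labels)
  # rings are concentric but occupy clearly distinct planes
  expect_lt(sep$centroidRatio, 0.5)
  expect_gt(sep$planeAngle, pi / 4)
  # single-gait recording: one ring, low radius spread
  one <- selfEmbed(generateUndulation(undulationParams(noiseSd = 0,
                                                       durationS = 30,
                                                       seed = 7)))
  r <- sqrt(rowSums(amplitudes(one)^2))
  expect_lt(sd(r) / mean(r), 0.3)
  expect_error(PostureRecording(matrix(numeric(0), 0, 10)),
               "at least one frame")
})

test_that("injected within-cycle speed modulation yields a bimodal profile", {
  # slow wave: the discrete frame-to-frame lag is well under one 15-deg bin,
  # so profile extremes land at the phases the modulation dictates — the
  # cycle is slowest where |a1| peaks (phases 0 and pi) and fastest in
  # quadrature, the swimming phenomenology
  rec <- generateUndulation(undulationParams(frequencyHz = 0.5,
                                             durationS = 120, noiseSd = 0,
                                             seed = 71))
  prof <- phaseSpeedProfile(selfEmbed(rec))
  ms <- prof@meanSpeed
  binW <- 2 * pi / prof@nBins
  circDist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  minima <- prof@binCenters[order(ms)[1:2]]
  maxima <- prof@binCenters[order(-ms)[1:2]]
  expect_true(all(vapply(minima, function(m)
    min(circDist(m, 0), circDist(m, pi)) <= binW, logical(1))))
  expect_true(all(vapply(maxima, function(m)
    min(circDist(m, pi / 2), circDist(m, -pi / 2)) <= binW, logical(1))))

  # swim defaults (2 Hz at 14 Hz sampling): still clearly bimodal, with the
  # two speed minima half a cycle apart
  rec2 <- generateUndulation(undulationParams(durationS = 60, noiseSd = 0,
                                              seed = 72))
  prof2 <- phaseSpeedProfile(selfEmbed(rec2))
  ms2 <- prof2@meanSpeed
  expect_gt(max(ms2) / min(ms2), 1.3)
  m2 <- prof2@binCenters[order(ms2)[1:2]]
  expect_equal(circDist(m2[1], m2[2]), pi, tolerance = 2 * binW / pi)
})
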