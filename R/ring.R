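#' Trajectory speed in eigenworm space
#'
#' Speed at frame t is the Euclidean distance between subsequent points in
#' eigenworm amplitude space multiplied by the sampling frequency:
#' \code{speed[t] = ||a[t+1, ] - a[t, ]|| * fs}, in amplitude units per
#' second.
#'
#' @param traj an [AmplitudeTrajectory-class] (or bare T x K matrix, in which
#'   case \code{samplingRate} is used).
#' @param samplingRate sampling rate in Hz for matrix input (default 14).
#' @return Numeric vector of length T - 1, all entries >= 0.
#' @export
trajectorySpeed <- function(traj, samplingRate = 14) {
  if (is(traj, "AmplitudeTrajectory")) {
    A <- amplitudes(traj)
    fs <- samplingRate(traj)
  } else {
    A <- as.matrix(traj)
    fs <- samplingRate
  }
  if (nrow(A) < 2L)
    stop("need at least 2 frames to compute a speed", call. = FALSE)
  d <- diff(A)
  sqrt(rowSums(d * d)) * fs
}

# Analytic signal via FFT: positive frequencies doubled, negative zeroed.
# Matches the discrete convention of standard signal-processing libraries.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of the locomotor cycle
#'
#' Phase of the analytic signal (Hilbert transform) of the mean-subtracted
#' first eigenworm amplitude, one value per frame in \code{(-pi, pi]}. For a
#' sinusoidal amplitude the unwrapped phase advances at \code{2*pi*f} per
#' second, increasing in the direction of temporal progression of the wave.
#' The transform has edge artefacts over roughly the first and last half
#' second; callers pooling phase statistics should drop those frames (see
#' \code{edgeTrim} in [phaseSpeedProfile()]).
#'
#' @param a1 numeric vector (first eigenworm amplitude), length >= 8, with
#'   nonzero variance.
#' @return Numeric vector of phases in \code{(-pi, pi]}, same length as
#'   \code{a1}.
#' @export
analyticPhase <- function(a1) {
  a1 <- as.numeric(a1)
  if (length(a1) < 8L)
    stop("need at least 8 frames for a phase estimate", call. = FALSE)
  if (stats::sd(a1) == 0 || !all(is.finite(a1)))
    stop("degenerate signal: first eigenworm amplitude is constant or non-finite",
         call. = FALSE)
  ph <- Arg(.analyticSignal(a1 - mean(a1)))
  ph[ph <= -pi] <- pi   # map the -pi edge onto (-pi, pi]
  ph
}

#' Bin speeds by phase around the locomotor cycle
#'
#' Partitions the circle \code{(-pi, pi]} into \code{nBins} equal bins and
#' averages the speed samples falling in each. Speed at frame t is paired
#' with the phase at frame t. To pool several recordings, concatenate their
#' (phase, speed) pairs before calling, or use [phaseSpeedProfile()].
#'
#' @param phase numeric vector of phases in \code{(-pi, pi]}.
#' @param speed numeric vector, same length as \code{phase}.
#' @param nBins number of bins, >= 4 (default 24, i.e. 15-degree bins).
#' @return A [PhaseSpeedProfile-class]; empty bins carry \code{NA}.
#' @export
phaseBinnedSpeed <- function(phase, speed, nBins = 24) {
  phase <- as.numeric(phase); speed <- as.numeric(speed)
  if (length(phase) != length(speed))
    stop("phase and speed must have the same length", call. = FALSE)
  if (nBins < 4) stop("nBins must be >= 4", call. = FALSE)
  nBins <- as.integer(nBins)
  width <- 2 * pi / nBins
  idx <- ceiling((phase + pi) / width)
  idx[idx < 1L] <- 1L; idx[idx > nBins] <- nBins
  counts <- tabulate(idx, nbins = nBins)
  sums <- vapply(seq_len(nBins), function(b) sum(speed[idx == b]), numeric(1))
  meanSpeed <- ifelse(counts > 0L, sums / counts, NA_real_)
  centers <- -pi + (seq_len(nBins) - 0.5) * width
  new("PhaseSpeedProfile", binCenters = centers, meanSpeed = meanSpeed,
      binCounts = as.integer(counts), nBins = nBins)
}

#' Phase-resolved speed profile of one or more amplitude trajectories
#'
#' For each trajectory: computes the Euclidean speed in amplitude space, the
#' analytic-signal phase of the first amplitude, drops \code{edgeTrim}
#' seconds at each end (Hilbert edge artefacts), then pools all (phase,
#' speed) pairs across recordings and bins them. Phase is computed per
#' recording before pooling, so recordings need not share a time origin.
#'
#' @param trajs an [AmplitudeTrajectory-class] or a list of them.
#' @param nBins number of phase bins (default 24).
#' @param edgeTrim seconds discarded at each end of every recording before
#'   pooling (default 0.5).
#' @return A [PhaseSpeedProfile-class].
#' @export
phaseSpeedProfile <- function(trajs, nBins = 24, edgeTrim = 0.5) {
  if (is(trajs, "AmplitudeTrajectory")) trajs <- list(trajs)
  allPhase <- numeric(); allSpeed <- numeric()
  for (tr in trajs) {
    A <- amplitudes(tr)
    if (nrow(A) < 9L) next
    sp <- trajectorySpeed(tr)
    ph <- analyticPhase(A[, 1])[-nrow(A)]   # phase at frame t pairs speed t
    drop <- ceiling(edgeTrim * samplingRate(tr))
    keep <- seq_along(sp) > drop & seq_along(sp) <= length(sp) - drop
    allPhase <- c(allPhase, ph[keep])
    allSpeed <- c(allSpeed, sp[keep])
  }
  if (length(allPhase) == 0L)
    stop("no usable frames after edge trimming", call. = FALSE)
  phaseBinnedSpeed(allPhase, allSpeed, nBins)
}

#' 2D Gaussian kernel density estimate of amplitude distributions
#'
#' Smooths the joint distribution of two eigenworm amplitudes with a
#' Gaussian kernel whose covariance is the data covariance scaled by Scott's
#' rule, \code{n^(-2/(d+4))} with d = 2 (linear bandwidth factor
#' \code{n^(-1/6)}) — the convention of covariance-scaled Gaussian KDE. The
#' density is evaluated on a regular grid spanning the data range plus 3
#' marginal bandwidths, so its Riemann sum is within a few parts per
#' thousand of 1.
#'
#' @param points T x 2 matrix (or [AmplitudeTrajectory-class], first two
#'   columns used) of amplitudes, T >= 10, nonsingular 2D covariance.
#' @param gridSize grid points per axis (default 128).
#' @return A [DensityGrid-class].
#' @examples
#' pts <- cbind(cos(seq(0, 6 * pi, length = 200)),
#'              sin(seq(0, 6 * pi, length = 200))) + 0.05
#' g <- amplitudeDensity(pts)
#' densityMass(g)
#' @export
amplitudeDensity <- function(points, gridSize = 128) {
  if (is(points, "AmplitudeTrajectory"))
    points <- amplitudes(points)[, 1:2, drop = FALSE]
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have 2 columns", call. = FALSE)
  n <- nrow(points)
  if (n < 10L) stop("need at least 10 points", call. = FALSE)
  Sig <- stats::cov(points)
  if (!is.finite(determinant(Sig)$modulus) || det(Sig) <= 1e-300)
    stop("degenerate data: 2D covariance is singular (collinear points)",
         call. = FALSE)
  H <- Sig * n^(-1 / 3)            # kernel covariance, Scott's rule squared
  bw <- sqrt(diag(H))              # marginal bandwidths
  x <- seq(min(points[, 1]) - 3 * bw[1], max(points[, 1]) + 3 * bw[1],
           length.out = gridSize)
  y <- seq(min(points[, 2]) - 3 * bw[2], max(points[, 2]) + 3 * bw[2],
           length.out = gridSize)
  Hinv <- solve(H)
  norm <- 1 / (2 * pi * sqrt(det(H)) * n)
  dens <- matrix(0, gridSize, gridSize)
  # accumulate kernels in chunks of grid rows to bound memory
  grid <- cbind(rep(x, times = gridSize), rep(y, each = gridSize))
  chunk <- 4096L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(grid))
    dx <- outer(grid[rows, 1], points[, 1], `-`)
    dy <- outer(grid[rows, 2], points[, 2], `-`)
    q <- Hinv[1, 1] * dx * dx + 2 * Hinv[1, 2] * dx * dy + Hinv[2, 2] * dy * dy
    dens[rows] <- rowSums(exp(-0.5 * q)) * norm
  }
  new("DensityGrid", x = x, y = y, density = dens, bandwidth = H)
}

#' Total probability mass of a density grid
#'
#' Riemann sum of the density over its grid; close to 1 when the grid covers
#' the data with the default 3-bandwidth margin.
#'
#' @param grid a [DensityGrid-class].
#' @return A number in [0, 1] up to quadrature error.
#' @export
densityMass <- function(grid) {
  stopifnot(is(grid, "DensityGrid"))
  dx <- diff(grid@x[1:2]); dy <- diff(grid@y[1:2])
  sum(grid@density) * dx * dy
}

#' Fraction of frames collapsed toward the ring center
#'
#' During coordinated undulation the first two amplitudes stay near a ring
#' of roughly constant radius; coordination lapses collapse the trajectory
#' toward the origin. This statistic is the fraction of frames whose radius
#' \code{||a||} is at or below \code{coreFraction} times the median radius —
#' near 0 for a clean ring, rising with the prevalence of lapses (and 1 in
#' the limit of a cloud fully collapsed onto the origin).
#'
#' @param points T x 2 amplitudes (or [AmplitudeTrajectory-class]), T >= 10.
#' @param coreFraction radius threshold as a fraction of the median radius,
#'   in (0, 1) (default 0.5).
#' @return Fraction in [0, 1].
#' @export
ringOccupancy <- function(points, coreFraction = 0.5) {
  if (is(points, "AmplitudeTrajectory"))
    points <- amplitudes(points)[, 1:2, drop = FALSE]
  points <- as.matrix(points)
  if (nrow(points) < 10L) stop("need at least 10 points", call. = FALSE)
  if (coreFraction <= 0 || coreFraction >= 1)
    stop("coreFraction must lie in (0, 1)", call. = FALSE)
  r <- sqrt(rowSums(points^2))
  if (all(r == 0))
    stop("degenerate data: all points at the origin", call. = FALSE)
  # <= so that a fully collapsed cloud (median radius 0) counts as occupied
  mean(r <= coreFraction * stats::median(r))
}

#' Self-basis embedding of a gait-transition recording
#'
#' For a recording that spans a gait transition (e.g. swimming to crawling),
#' eigendecomposes that recording's own posture covariance and returns the
#' first-k amplitude trajectory. In such recordings the two gaits trace
#' distinct rings occupying different planes of this embedding.
#'
#' @param recording a [PostureRecording-class].
#' @param k number of eigenworms to keep (default 3, for 3D inspection).
#' @return An [AmplitudeTrajectory-class].
#' @seealso [ringSeparation()] to quantify the two-ring structure.
#' @export
transitionEmbedding <- function(recording, k = 3) {
  stopifnot(is(recording, "PostureRecording"))
  mc <- pooledMeanCovariance(recording)
  basis <- eigenDecompose(mc$covariance, mean = mc$mean,
                          source = sprintf("self:%s", recordingId(recording)))
  projectAmplitudes(recording, basis, k = k)
}

#' Quantify the separation of two rings in an embedding
#'
#' Given a labelled split of an amplitude trajectory into two epochs (e.g.
#' swimming frames vs crawling frames), measures how distinct the two rings
#' are. Two complementary statistics are returned: the distance between
#' epoch centroids relative to the within-epoch root-mean-square spread, and
#' the largest principal angle between the two epochs' best-fit ring planes
#' (the 2D principal subspaces of each epoch). Rhythmic gaits trace rings
#' centered near the origin of the shared embedding, so concentric but
#' differently oriented rings separate in plane angle even when their
#' centroids coincide.
#'
#' @param traj an [AmplitudeTrajectory-class] with k >= 3 columns, or a bare
#'   T x k matrix.
#' @param labels vector with exactly two distinct values, one per frame.
#' @return list with \code{centroidDistance}, \code{withinSpread} (mean of
#'   the two epochs' RMS spreads), \code{centroidRatio} (distance / spread),
#'   and \code{planeAngle} (radians, in [0, pi/2]).
#' @export
ringSeparation <- function(traj, labels) {
  A <- if (is(traj, "AmplitudeTrajectory")) amplitudes(traj) else as.matrix(traj)
  if (length(labels) != nrow(A))
    stop("labels must have one entry per frame", call. = FALSE)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("labels must contain exactly two distinct values", call. = FALSE)
  parts <- lapply(lev, function(l) A[labels == l, , drop = FALSE])
  cents <- lapply(parts, colMeans)
  spreads <- vapply(seq_along(parts), function(i) {
    d <- sweep(parts[[i]], 2L, cents[[i]])
    sqrt(mean(rowSums(d * d)))
  }, numeric(1))
  cd <- sqrt(sum((cents[[1]] - cents[[2]])^2))
  planes <- lapply(seq_along(parts), function(i) {
    d <- sweep(parts[[i]], 2L, cents[[i]])
    svd(d, nu = 0, nv = 2)$v   # ring plane: top-2 right singular vectors
  })
  # principal angles between the two 2D subspaces
  sv <- svd(crossprod(planes[[1]], planes[[2]]))$d
  sv <- pmin(pmax(sv, -1), 1)
  list(centroidDistance = cd,
       withinSpread = mean(spreads),
       centroidRatio = cd / mean(spreads),
       planeAngle = max(acos(sv)))
}
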