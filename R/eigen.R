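#' Pooled mean posture and covariance across recordings
#'
#' Computes the grand mean over all pooled frames and the population
#' covariance C(s, s') = <(theta(s) - <theta>)(theta(s') - <theta>)>, the
#' bracket average running over every frame of every recording (divide by the
#' total frame count, not T - 1). Pooling frames from all developmental
#' stages of one gait is the default way eigenworm bases are defined here:
#' per-stage covariances have nearly identical eigenvectors, so a single
#' basis allows all stages to be compared in the same coordinates.
#'
#' @param recordings a [PostureRecording-class] or a list of them, all with
#'   the same number of segment angles.
#' @return list with \code{mean} (length-S vector) and \code{covariance}
#'   (S x S symmetric matrix).
#' @examples
#' rec <- PostureRecording(rbind(c(1, 0), c(-1, 0)))
#' pooledMeanCovariance(rec)$covariance   # [[1, 0], [0, 0]]
#' @export
pooledMeanCovariance <- function(recordings) {
  if (is(recordings, "PostureRecording")) recordings <- list(recordings)
  if (length(recordings) == 0L)
    stop("no recordings supplied", call. = FALSE)
  S <- nSegments(recordings[[1]])
  for (r in recordings)
    if (nSegments(r) != S)
      stop("all recordings must have the same number of segment angles",
           call. = FALSE)
  X <- do.call(rbind, lapply(recordings, angles))
  if (nrow(X) < 2L)
    stop("need at least 2 pooled frames for a covariance", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nrow(X)
  C <- (C + t(C)) / 2   # enforce exact symmetry
  list(mean = mu, covariance = C)
}

#' Eigendecompose a posture covariance matrix
#'
#' Solves sum_s' C(s, s') mu_i(s') = lambda_i mu_i(s) for the eigenworms
#' mu_i and eigenvalues lambda_i. Eigenvalues are returned in descending
#' order, tiny negative values (numerical noise) clipped to zero. The sign of
#' each eigenworm is fixed so that its entry of largest absolute value is
#' positive — the eigenproblem is sign-ambiguous and a deterministic
#' convention keeps downstream outputs stable. Ties between (numerically)
#' equal eigenvalues are broken by the ascending index of each eigenworm's
#' dominant loading, and degenerate subspaces are reported via
#' \code{message()}.
#'
#' @param covariance symmetric S x S matrix (asymmetry beyond \code{tol} is
#'   an error).
#' @param mean optional length-S mean posture stored with the basis (default
#'   zeros).
#' @param source short description of the data the covariance came from.
#' @param tol symmetry tolerance (default 1e-9).
#' @return An [EigenDecomposition-class].
#' @examples
#' ed <- eigenDecompose(matrix(c(2, 1, 1, 2), 2))
#' eigenvalues(ed)          # 3 1
#' eigenworms(ed)           # columns (1,1)/sqrt(2), (1,-1)/sqrt(2)
#' @export
eigenDecompose <- function(covariance, mean = NULL, source = "unspecified",
                           tol = 1e-9) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance))
    stop("covariance must be square", call. = FALSE)
  if (max(abs(covariance - t(covariance))) > tol)
    stop(sprintf("covariance is asymmetric beyond tolerance %g", tol),
         call. = FALSE)
  S <- nrow(covariance)
  if (is.null(mean)) mean <- numeric(S)
  eg <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (any(lam < -1e-12 * max(abs(lam), 1)))
    warning("covariance has a substantially negative eigenvalue; clipping to 0",
            call. = FALSE)
  lam[lam < 0] <- 0
  vec <- eg$vectors

  # sign convention: dominant loading positive
  dom <- apply(vec, 2L, function(v) which.max(abs(v)))
  flip <- vec[cbind(dom, seq_len(S))] < 0
  vec[, flip] <- -vec[, flip]

  # stable tie-break among numerically equal eigenvalues
  scale <- max(lam, .Machine$double.eps)
  grp <- cumsum(c(TRUE, diff(lam) < -1e-10 * scale))
  if (anyDuplicated(grp)) {
    ord <- order(grp, dom)
    if (!identical(ord, seq_len(S))) {
      message("eigenDecompose: degenerate eigenvalue subspace; ties broken by dominant-loading index")
      lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]
      # numerically equal eigenvalues may swap order within a tie group;
      # restore exact monotonicity without changing the total variance
      gm <- tapply(lam, grp, mean)
      lam <- as.numeric(gm[as.character(grp)])
    }
  }

  tot <- sum(lam)
  vf <- if (tot > 0) lam / tot else rep(1 / S, S)
  new("EigenDecomposition", meanPosture = as.numeric(mean),
      eigenworms = vec, eigenvalues = lam, varianceFraction = vf,
      source = source)
}

#' Cumulative variance fraction captured by the first k eigenworms
#'
#' \code{sum(lambda[1:k]) / sum(lambda)}: the fraction of total posture
#' variance explained when postures are reconstructed from the first k
#' eigenworms.
#'
#' @param eigenvalues descending non-negative vector, or an
#'   [EigenDecomposition-class].
#' @param k number of leading eigenworms, \code{1 <= k <= S}.
#' @return A fraction in [0, 1].
#' @examples
#' cumulativeVariance(c(3, 1), 1)   # 0.75
#' @export
cumulativeVariance <- function(eigenvalues, k) {
  if (is(eigenvalues, "EigenDecomposition"))
    eigenvalues <- eigenvalues(eigenvalues)
  S <- length(eigenvalues)
  if (length(k) != 1L || k < 1 || k > S || k != round(k))
    stop(sprintf("k must be an integer in [1, %d]", S), call. = FALSE)
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero", call. = FALSE)
  sum(eigenvalues[seq_len(k)]) / tot
}

#' Project a recording onto an eigenworm basis
#'
#' Amplitude of eigenworm i at frame t is the inner product of the
#' mean-subtracted posture with mu_i:
#' \code{a[t, i] = <theta_t - meanPosture, mu_i>}. With \code{k = S} the
#' orthonormal basis is complete and reconstruction is exact.
#'
#' @param recording a [PostureRecording-class] (or a bare T x S matrix).
#' @param basis an [EigenDecomposition-class] with matching S.
#' @param k number of eigenworms to keep (default 2, the ring plane).
#' @return An [AmplitudeTrajectory-class] with T x k amplitudes.
#' @export
projectAmplitudes <- function(recording, basis, k = 2) {
  stopifnot(is(basis, "EigenDecomposition"))
  if (is(recording, "PostureRecording")) {
    X <- angles(recording)
    fs <- samplingRate(recording)
  } else {
    X <- as.matrix(recording)
    fs <- 14
  }
  S <- length(meanPosture(basis))
  if (ncol(X) != S)
    stop(sprintf("recording has %d segment angles but basis expects %d",
                 ncol(X), S), call. = FALSE)
  if (k < 1 || k > S)
    stop(sprintf("k must be in [1, %d]", S), call. = FALSE)
  A <- sweep(X, 2L, meanPosture(basis)) %*%
    eigenworms(basis)[, seq_len(k), drop = FALSE]
  new("AmplitudeTrajectory", amplitudes = unname(A), samplingRate = fs,
      basisId = basis@source)
}

#' Reconstruct postures from eigenworm amplitudes
#'
#' Inverse of [projectAmplitudes()]: \code{meanPosture + A \%*\% t(mu[, 1:k])}.
#'
#' @param traj an [AmplitudeTrajectory-class].
#' @param basis the [EigenDecomposition-class] it was projected with.
#' @return T x S matrix of reconstructed angles.
#' @export
reconstructPostures <- function(traj, basis) {
  stopifnot(is(traj, "AmplitudeTrajectory"), is(basis, "EigenDecomposition"))
  A <- amplitudes(traj)
  k <- ncol(A)
  sweep(A %*% t(eigenworms(basis)[, seq_len(k), drop = FALSE]), 2L,
        meanPosture(basis), `+`)
}

#' Compare two eigenworm bases mode by mode
#'
#' Absolute cosine similarity of corresponding eigenworms,
#' \code{|<mu_i^a, mu_i^b>|}, for the first k modes. Sign-invariant by
#' construction; 1 means identical shapes. Used to ask whether eigenworms are
#' conserved across developmental stages.
#'
#' @param basisA,basisB [EigenDecomposition-class] objects over the same S.
#' @param k number of leading modes to compare.
#' @return Numeric vector of k values in [0, 1].
#' @export
basisSimilarity <- function(basisA, basisB, k = 4) {
  stopifnot(is(basisA, "EigenDecomposition"), is(basisB, "EigenDecomposition"))
  S <- length(meanPosture(basisA))
  if (length(meanPosture(basisB)) != S)
    stop("bases must span the same number of segment angles", call. = FALSE)
  if (k < 1 || k > S)
    stop(sprintf("k must be in [1, %d]", S), call. = FALSE)
  sapply(seq_len(k), function(i)
    abs(sum(eigenworms(basisA)[, i] * eigenworms(basisB)[, i])))
}
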