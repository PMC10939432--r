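#' Participation ratio of an eigenvalue spectrum
#'
#' PR = (sum(lambda))^2 / sum(lambda^2), a continuous dimensionality measure
#' of a non-negative spectrum: 1 when all variance sits in one mode
#' (eigenvalues 1, 0, 0), N when it is spread evenly (1/3, 1/3, 1/3 gives
#' 3). Scale-invariant, so it does not depend on overall posture variance.
#'
#' @param eigenvalues non-negative numeric vector (or an
#'   [EigenDecomposition-class]); tiny negative values from numerical noise
#'   are clipped to 0.
#' @return A number in [1, N].
#' @examples
#' participationRatio(c(1, 0, 0))        # 1
#' participationRatio(c(1, 1, 1) / 3)    # 3
#' @export
participationRatio <- function(eigenvalues) {
  if (is(eigenvalues, "EigenDecomposition"))
    eigenvalues <- eigenvalues(eigenvalues)
  lam <- as.numeric(eigenvalues)
  if (any(!is.finite(lam)))
    stop("eigenvalues must be finite", call. = FALSE)
  if (any(lam < -1e-10 * max(abs(lam))))
    stop("eigenvalues must be non-negative", call. = FALSE)
  lam[lam < 0] <- 0
  s2 <- sum(lam^2)
  if (s2 == 0)
    stop("degenerate spectrum: all eigenvalues are zero", call. = FALSE)
  sum(lam)^2 / s2
}

#' Participation ratio of a single recording
#'
#' Dimensionality of one recording's own posture covariance (population
#' normalized): eigenvalues are computed per recording, not from a pooled
#' basis, and fed to [participationRatio()]. Scale-invariant: multiplying
#' all angles by a constant leaves the PR unchanged.
#'
#' @param recording a [PostureRecording-class].
#' @return PR in [1, S].
#' @export
prPerRecording <- function(recording) {
  stopifnot(is(recording, "PostureRecording"))
  mc <- pooledMeanCovariance(recording)
  lam <- eigen(mc$covariance, symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) <= 0)
    stop(sprintf("degenerate recording '%s': constant posture",
                 recordingId(recording)), call. = FALSE)
  participationRatio(pmax(lam, 0))
}

#' Per-recording participation ratios grouped by stage
#'
#' Computes the PR of every usable recording and tabulates it with its gait
#' and stage. Recordings shorter than \code{minFrames} are excluded from
#' group statistics and reported via \code{message()} (default 28 frames,
#' about 2 s at 14 Hz — PR estimates on fewer frames are not meaningful).
#'
#' @param recordings list of [PostureRecording-class] objects.
#' @param minFrames minimum usable recording length (default 28).
#' @return data.frame with columns \code{recordingId}, \code{gait},
#'   \code{stage}, \code{nFrames}, \code{pr}.
#' @seealso [stageSummary()], [pairwiseStageTests()]
#' @export
prTable <- function(recordings, minFrames = 28) {
  if (is(recordings, "PostureRecording")) recordings <- list(recordings)
  rows <- list()
  for (rec in recordings) {
    if (nFrames(rec) < minFrames) {
      message(sprintf("prTable: excluded '%s' (%d frames < minimum %d)",
                      recordingId(rec), nFrames(rec), minFrames))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      recordingId = recordingId(rec), gait = gait(rec), stage = stage(rec),
      nFrames = nFrames(rec), pr = prPerRecording(rec),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no recordings passed the minimum-length filter", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage-wise summaries of participation ratios
#'
#' Mean, interquartile range and group size of the PR distribution per
#' developmental stage.
#'
#' @param prtab a data.frame from [prTable()].
#' @return data.frame with columns \code{stage}, \code{n}, \code{meanPR},
#'   \code{q25}, \code{q75}, \code{iqr}.
#' @export
stageSummary <- function(prtab) {
  stopifnot(all(c("stage", "pr") %in% names(prtab)))
  stages <- unique(prtab$stage)
  out <- do.call(rbind, lapply(stages, function(s) {
    x <- prtab$pr[prtab$stage == s]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(stage = s, n = length(x), meanPR = mean(x),
               q25 = q[1], q75 = q[2], iqr = q[2] - q[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise two-sample tests of PR between developmental stages
#'
#' Runs all G*(G-1)/2 two-sided two-sample t-tests between stage groups,
#' either the standard equal-variance test or Welch's (default, robust to
#' unequal group variances). Significance uses the Bonferroni-adjusted
#' threshold \code{alpha / nComparisons}; with 6 stages that is 0.05/15 =
#' 0.0033. Pairs involving a group with fewer than 2 recordings are skipped
#' with a warning but still counted in the correction.
#'
#' @param prtab data.frame from [prTable()] (needs \code{stage}, \code{pr}).
#' @param alpha family-wise error rate before correction (default 0.05).
#' @param variant \code{"welch"} (default) or \code{"standard"}
#'   (equal-variance).
#' @return data.frame with columns \code{stageA}, \code{stageB},
#'   \code{tStatistic}, \code{pValue}, \code{testVariant},
#'   \code{significant}; attributes \code{adjustedAlpha} and
#'   \code{nComparisons}.
#' @examples
#' tab <- data.frame(stage = rep(c("youngL1", "adult"), each = 3),
#'                   pr = c(4, 5, 6, 1, 2, 3))
#' tests <- pairwiseStageTests(tab, variant = "standard")
#' tests$tStatistic   # +/- 3.674 (pooled-variance t, df = 4)
#' @export
pairwiseStageTests <- function(prtab, alpha = 0.05,
                               variant = c("welch", "standard")) {
  variant <- match.arg(variant)
  stopifnot(all(c("stage", "pr") %in% names(prtab)))
  groups <- split(prtab$pr, prtab$stage)
  # keep encounter order of stages rather than alphabetical
  groups <- groups[unique(prtab$stage)]
  G <- length(groups)
  if (G < 2L)
    stop("need at least two stage groups for pairwise tests", call. = FALSE)
  nComparisons <- as.integer(G * (G - 1L) / 2L)
  adjAlpha <- alpha / nComparisons
  rows <- list()
  pairs <- utils::combn(names(groups), 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (length(groups[[a]]) < 2L || length(groups[[b]]) < 2L) {
      warning(sprintf("pairwiseStageTests: skipping %s vs %s (a group has < 2 recordings)",
                      a, b), call. = FALSE)
      next
    }
    tt <- stats::t.test(groups[[a]], groups[[b]],
                        var.equal = (variant == "standard"))
    rows[[length(rows) + 1L]] <- data.frame(
      stageA = a, stageB = b,
      tStatistic = unname(tt$statistic), pValue = tt$p.value,
      testVariant = variant, significant = tt$p.value < adjAlpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stageA = character(), stageB = character(),
               tStatistic = numeric(), pValue = numeric(),
               testVariant = character(), significant = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "adjustedAlpha") <- adjAlpha
  attr(out, "nComparisons") <- nComparisons
  out
}
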