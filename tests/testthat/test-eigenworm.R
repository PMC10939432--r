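test_that("pooled mean and covariance match hand-computed examples", {
  # frames (1,0) and (-1,0): mean (0,0), population covariance [[1,0],[0,0]]
  rec <- PostureRecording(rbind(c(1, 0), c(-1, 0)))
  mc <- pooledMeanCovariance(rec)
  expect_equal(mc$mean, c(0, 0))
  expect_equal(mc$covariance, rbind(c(1, 0), c(0, 0)))

  # constant posture: zero covariance
  recC <- PostureRecording(matrix(rep(c(0.2, -0.1, 0.3), each = 5), 5, 3))
  mcC <- pooledMeanCovariance(recC)
  expect_equal(mcC$mean, c(0.2, -0.1, 0.3))
  expect_equal(mcC$covariance, matrix(0, 3, 3))

  # identical sine on every segment: perfectly correlated, rank 1
  x <- sin(2 * pi * seq(0, 3, by = 0.05))
  recS <- PostureRecording(matrix(rep(x, 4), ncol = 4))
  C <- pooledMeanCovariance(recS)$covariance
  expect_equal(max(abs(C - C[1, 1])), 0, tolerance = 1e-12)
})

test_that("pooled covariance equals the brute-force double loop", {
  set.seed(71)
  for (rep in 1:5) {
    T <- sample(20:200, 1); S <- sample(3:10, 1)
    X <- matrix(rnorm(T * S, sd = 0.3), T, S)
    split <- sort(sample(seq_len(T - 2), 2))
    recs <- list(
      PostureRecording(X[1:split[1], , drop = FALSE]),
      PostureRecording(X[(split[1] + 1):split[2], , drop = FALSE]),
      PostureRecording(X[(split[2] + 1):T, , drop = FALSE]))
    mc <- pooledMeanCovariance(recs)
    expect_equal(mc$covariance, bruteCovariance(X), tolerance = 1e-12)
    expect_equal(mc$mean, colMeans(X), tolerance = 1e-12)
  }
})

test_that("eigendecomposition matches closed-form small cases", {
  ed <- suppressMessages(eigenDecompose(diag(3)))
  expect_equal(eigenvalues(ed), c(1, 1, 1))

  ed2 <- eigenDecompose(diag(c(3, 2, 1)))
  expect_equal(eigenvalues(ed2), c(3, 2, 1))
  expect_equal(abs(eigenworms(ed2)), diag(3), tolerance = 1e-12)

  # [[2,1],[1,2]]: eigenvalues 3, 1; eigenworms (1,1)/sqrt(2), (1,-1)/sqrt(2)
  ed3 <- eigenDecompose(rbind(c(2, 1), c(1, 2)))
  expect_equal(eigenvalues(ed3), c(3, 1))
  expect_equal(eigenworms(ed3)[, 1], c(1, 1) / sqrt(2))
  expect_equal(abs(eigenworms(ed3)[, 2]), c(1, 1) / sqrt(2))
  expect_error(eigenDecompose(rbind(c(1, 0.5), c(0, 1))), "asymmetric")
})

test_that("eigenvector sign and ordering conventions are deterministic", {
  set.seed(5)
  X <- matrix(rnorm(600), 60, 10)
  C <- bruteCovariance(X)
  ed <- eigenDecompose(C)
  # dominant loading of every eigenworm is positive
  signs <- apply(eigenworms(ed), 2, function(v) v[which.max(abs(v))])
  expect_true(all(signs > 0))
  # orthonormal within 1e-8 and descending
  expect_equal(crossprod(eigenworms(ed)), diag(10), tolerance = 1e-8)
  expect_false(is.unsorted(rev(eigenvalues(ed))))
  # trace conservation
  expect_equal(sum(eigenvalues(ed)), sum(diag(C)), tolerance = 1e-10)
})

test_that("cumulative variance fraction follows the eigenvalue formula", {
  expect_equal(cumulativeVariance(c(3, 1), 1), 0.75)
  expect_equal(cumulativeVariance(c(3, 1), 2), 1.0)
  lam <- c(5, 3, 1.5, 0.4, 0.1)
  expect_equal(cumulativeVariance(lam, 5), 1.0)
  expect_true(!is.unsorted(sapply(1:5, cumulativeVariance,
                                  eigenvalues = lam)))
  expect_error(cumulativeVariance(lam, 0), "k must be")
  expect_error(cumulativeVariance(lam, 6), "k must be")
})

test_that("amplitude projection inverts exactly with the full basis", {
  set.seed(9)
  X <- matrix(rnorm(300, sd = 0.4), 30, 10)
  rec <- PostureRecording(X)
  mc <- pooledMeanCovariance(rec)
  basis <- eigenDecompose(mc$covariance, mean = mc$mean)

  # frame equal to the mean projects to zero
  tr0 <- projectAmplitudes(matrix(mc$mean, 1), basis, k = 10)
  expect_equal(as.numeric(amplitudes(tr0)), numeric(10), tolerance = 1e-12)

  # mean + first eigenworm projects to (1, 0, ..., 0)
  tr1 <- projectAmplitudes(matrix(mc$mean + eigenworms(basis)[, 1], 1),
                           basis, k = 10)
  expect_equal(as.numeric(amplitudes(tr1)), c(1, rep(0, 9)),
               tolerance = 1e-10)

  # completeness: k = S reconstruction is exact
  trS <- projectAmplitudes(rec, basis, k = 10)
  expect_lt(max(abs(reconstructPostures(trS, basis) - X)), 1e-10)
  expect_error(projectAmplitudes(matrix(0, 2, 4), basis), "segment angles")
})

test_that("a noiseless travelling wave has exactly two dominant modes", {
  for (wl in c(1.0, 2.0)) {
    rec <- waveRecording(200, wavelengthBL = wl)   # > 3 cycles at 0.5 Hz
    mc <- pooledMeanCovariance(rec)
    lam <- eigenvalues(suppressMessages(eigenDecompose(mc$covariance)))
    expect_equal(sum(lam > 1e-10 * sum(lam)), 2L)
  }
})

test_that("basis similarity is sign-invariant and matches rotations", {
  ed <- eigenDecompose(diag(c(3, 2, 1)))
  expect_equal(basisSimilarity(ed, ed, 3), rep(1, 3))
  flipped <- ed
  flipped@eigenworms <- -eigenworms(ed)
  expect_equal(basisSimilarity(ed, flipped, 3), rep(1, 3))
  # axis-aligned vs 45-degree rotated 2D basis: similarities sqrt(2)/2
  a <- eigenDecompose(diag(c(2, 1)))
  th <- pi / 4
  rot <- a
  rot@eigenworms <- cbind(c(cos(th), sin(th)), c(sin(th), -cos(th)))
  expect_equal(basisSimilarity(a, rot, 2), rep(sqrt(2) / 2, 2))
  expect_error(basisSimilarity(a, rot, 3), "k must be")
})
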