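# Independent oracles and tiny fixture builders, kept deliberately naive so
# they stay independent of the implementation under test.

# population covariance by explicit double loop over segment pairs
bruteCovariance <- function(X) {
  S <- ncol(X); T <- nrow(X)
  mu <- colMeans(X)
  C <- matrix(0, S, S)
  for (i in seq_len(S))
    for (j in seq_len(S))
      C[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / T
  C
}

# travelling wave built directly from the closed form (no generator involved)
waveMatrix <- function(T, S = 10, A = 0.6, wavelengthBL = 1.0, freqHz = 0.5,
                       fs = 14) {
  t <- (seq_len(T) - 1) / fs
  s <- seq_len(S)
  outer(t, s, function(t, s) A * sin(2 * pi * s / (S * wavelengthBL) -
                                       2 * pi * freqHz * t))
}

waveRecording <- function(T, ..., fs = 14, gait = "swimming",
                          stage = "adult", id = "wave") {
  PostureRecording(waveMatrix(T, fs = fs, ...), gait = gait, stage = stage,
                   recordingId = id, samplingRate = fs)
}

# simple phase unwrap (cumulative 2*pi corrections)
unwrapPhase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

writeRecordingFile <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# a tiny well-formed 11-column line
recLine <- function(t, angles = rep(0.1, 10)) {
  paste(sprintf("%.6f", c(t, angles)), collapse = "\t")
}
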