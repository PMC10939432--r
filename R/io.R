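## Tracked-posture text format: 11 whitespace/tab-delimited columns, the
## first timestamps (s), the remaining S = 10 segment angles (radians).

.GAIT_ALIASES <- c(
  "swimming" = "swimming", "swim" = "swimming", "swimmer" = "swimming",
  "crawling" = "crawling", "crawl" = "crawling", "crawler" = "crawling",
  "transition" = "transition", "transitions" = "transition"
)

.STAGE_ALIASES <- c(
  "youngl1" = "youngL1", "young l1" = "youngL1", "young_l1" = "youngL1",
  "young-l1" = "youngL1", "l1_young" = "youngL1", "l1 young" = "youngL1",
  "l1young" = "youngL1", "earlyl1" = "youngL1", "early l1" = "youngL1",
  "latel1" = "lateL1", "late l1" = "lateL1", "late_l1" = "lateL1",
  "late-l1" = "lateL1", "l1_late" = "lateL1", "l1 late" = "lateL1",
  "l1late" = "lateL1",
  "l2" = "L2", "l3" = "L3", "l4" = "L4",
  "adult" = "adult", "adults" = "adult", "day1adult" = "adult",
  "day-1 adult" = "adult", "day 1 adult" = "adult", "young adult" = "adult"
)

.normalizeGait <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.GAIT_ALIASES[key])
  out[is.na(out)] <- "unknown"
  out
}

.normalizeStage <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.STAGE_ALIASES[key])
  out[is.na(out)] <- "unknown"
  out
}

#' Read a tracked-posture recording from the 11-column text format
#'
#' Parses one whitespace- or tab-delimited text file with one row per frame:
#' column 1 holds timestamps in seconds, the remaining columns the
#' inter-segment angles in radians (10 by default). An optional single header
#' line whose first token is non-numeric is skipped. Rows containing a
#' non-finite angle (NaN from tracking failures) are dropped and the count is
#' reported via \code{message()}.
#'
#' @param path path to the text file.
#' @param gait,stage metadata attached to the returned object (see
#'   [PostureRecording()]); defaults to \code{"unknown"}.
#' @param samplingRate nominal sampling rate in Hz (default 14).
#' @param nAngles expected number of angle columns (default 10).
#' @return A validated [PostureRecording-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' rec <- generateUndulation(undulationParams(durationS = 2, seed = 1))
#' writeRecording(rec, f)
#' rec2 <- readRecording(f, gait = "swimming", stage = "adult")
#' nFrames(rec2)
#' @export
readRecording <- function(path, gait = "unknown", stage = "unknown",
                          samplingRate = 14, nAngles = 10) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("empty recording: %s has no data rows", path), call. = FALSE)
  tokens <- strsplit(trimws(lines), "[ \t]+")
  lineNo <- seq_along(lines)

  # optional single header line: first token non-numeric (and not NaN/NA)
  first <- tokens[[1]][1]
  if (is.na(suppressWarnings(as.numeric(first))) &&
      !toupper(first) %in% c("NAN", "NA")) {
    tokens <- tokens[-1]
    lineNo <- lineNo[-1]
    if (length(tokens) == 0L)
      stop(sprintf("empty recording: %s has only a header", path),
           call. = FALSE)
  }

  want <- nAngles + 1L
  counts <- lengths(tokens)
  if (any(counts != want)) {
    bad <- which(counts != want)[1]
    stop(sprintf(
      "format error in %s at line %d: expected %d columns, found %d",
      path, lineNo[bad], want, counts[bad]), call. = FALSE)
  }

  flat <- unlist(tokens, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- is.na(vals) & !toupper(flat) %in% c("NAN", "NA")
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "parse error in %s at line %d: non-numeric token '%s'",
      path, lineNo[(i - 1L) %/% want + 1L], flat[i]), call. = FALSE)
  }
  mat <- matrix(vals, ncol = want, byrow = TRUE)

  ts <- mat[, 1]
  ang <- mat[, -1, drop = FALSE]
  keep <- is.finite(ts) & apply(ang, 1L, function(r) all(is.finite(r)))
  if (!all(keep))
    message(sprintf("readRecording: dropped %d frame(s) with non-finite values in %s",
                    sum(!keep), basename(path)))
  if (!any(keep))
    stop(sprintf("empty recording: %s has no usable rows after cleaning", path),
         call. = FALSE)
  PostureRecording(ang[keep, , drop = FALSE], timestamps = ts[keep],
                   gait = .normalizeGait(gait), stage = .normalizeStage(stage),
                   recordingId = sub("\\.[^.]*$", "", basename(path)),
                   samplingRate = samplingRate)
}

#' Write a recording in the 11-column text format
#'
#' Emits the same delimited layout the reader consumes: timestamps in the
#' first column, angles in the remaining ones, tab-separated, 6 decimal
#' places. Round-tripping reproduces values to that printed precision.
#'
#' @param recording a [PostureRecording-class].
#' @param path output file path.
#' @param digits decimal places to print (default 6).
#' @return Invisibly, \code{path}.
#' @export
writeRecording <- function(recording, path, digits = 6) {
  stopifnot(is(recording, "PostureRecording"))
  fmt <- sprintf("%%.%df", digits)
  mat <- cbind(timestamps(recording), angles(recording))
  rows <- apply(mat, 1L, function(r) paste(sprintf(fmt, r), collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' Discover recordings in a gait/stage directory layout
#'
#' Walks two directory levels below \code{root} — gait on the first, stage on
#' the second — and returns a descriptor per \code{.txt} file found. Folder
#' names are matched case-insensitively against an alias table (e.g.
#' \code{"young L1"}, \code{"L1_young"} and \code{"youngL1"} all map to
#' \code{youngL1}); unrecognized names map to \code{"unknown"} and are
#' reported, not fatal. Non-\code{.txt} files are skipped with a message.
#'
#' @param root dataset root directory.
#' @return A data.frame with columns \code{path}, \code{gait}, \code{stage}
#'   (zero rows, with a warning, if nothing recognizable is found). File
#'   order within a folder is alphabetical; folders are visited in sorted
#'   order.
#' @export
discoverDataset <- function(root) {
  if (!dir.exists(root))
    stop(sprintf("dataset root does not exist: %s", root), call. = FALSE)
  out <- list()
  for (gaitDir in sort(list.dirs(root, recursive = FALSE))) {
    g <- .normalizeGait(basename(gaitDir))
    if (g == "unknown")
      message(sprintf("discoverDataset: unrecognized gait folder '%s'",
                      basename(gaitDir)))
    for (stageDir in sort(list.dirs(gaitDir, recursive = FALSE))) {
      s <- .normalizeStage(basename(stageDir))
      if (s == "unknown")
        message(sprintf("discoverDataset: unrecognized stage folder '%s'",
                        basename(stageDir)))
      files <- sort(list.files(stageDir, full.names = TRUE))
      files <- files[!dir.exists(files)]
      isTxt <- grepl("\\.txt$", files, ignore.case = TRUE)
      if (any(!isTxt))
        message(sprintf("discoverDataset: skipped %d non-.txt file(s) in %s",
                        sum(!isTxt), stageDir))
      for (f in files[isTxt])
        out[[length(out) + 1L]] <- data.frame(
          path = f, gait = g, stage = s, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    warning(sprintf("discoverDataset: no recognizable .txt recordings under %s",
                    root), call. = FALSE)
    return(data.frame(path = character(), gait = character(),
                      stage = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
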