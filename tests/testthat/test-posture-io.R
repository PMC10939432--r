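test_that("a minimal well-formed 11-column file parses into T x 10 angles", {
  f <- writeRecordingFile(c(recLine(0), recLine(1 / 14), recLine(2 / 14)))
  rec <- readRecording(f, gait = "swimming", stage = "adult")
  expect_s4_class(rec, "PostureRecording")
  expect_equal(nFrames(rec), 3L)
  expect_equal(nSegments(rec), 10L)
  expect_equal(timestamps(rec), c(0, 1, 2) / 14, tolerance = 1e-5)
  expect_equal(gait(rec), "swimming")
  expect_equal(stage(rec), "adult")
})

test_that("malformed and non-numeric rows raise errors naming the line", {
  f <- writeRecordingFile(c(recLine(0),
                            paste(recLine(1 / 14), "0.5", sep = "\t"),
                            recLine(2 / 14)))
  expect_error(readRecording(f), "line 2")
  f2 <- writeRecordingFile(c(recLine(0), sub("0\\.100000", "oops",
                                             recLine(1 / 14))))
  expect_error(readRecording(f2), "line 2.*oops")
  f3 <- writeRecordingFile(character(0))
  expect_error(readRecording(f3), "empty recording")
  expect_error(readRecording(file.path(tempdir(), "does-not-exist.txt")),
               "not found")
})

test_that("rows containing NaN angles are dropped and counted", {
  lines <- c(recLine(0), sub("0\\.100000", "NaN", recLine(1 / 14)),
             recLine(2 / 14))
  f <- writeRecordingFile(lines)
  suppressWarnings(expect_message(rec <- readRecording(f), "dropped 1 frame"))
  expect_equal(nFrames(rec), 2L)
  expect_equal(timestamps(rec), c(0, 2) / 14, tolerance = 1e-5)
  # an all-NaN file is empty after cleaning
  f2 <- writeRecordingFile(sub("0\\.100000", "NaN", recLine(0)))
  expect_error(suppressMessages(readRecording(f2)), "no usable rows")
})

test_that("a single non-numeric header line is skipped", {
  f <- writeRecordingFile(c(paste(c("time", sprintf("angle%d", 1:10)),
                                  collapse = "\t"),
                            recLine(0), recLine(1 / 14)))
  rec <- readRecording(f)
  expect_equal(nFrames(rec), 2L)
})

test_that("whitespace and tab delimiters are both accepted, order preserved", {
  ang <- matrix(seq(-0.5, 0.5, length.out = 30), 3, 10)
  sp <- apply(cbind(0:2 / 14, ang), 1,
              function(r) paste(sprintf("%.6f", r), collapse = "  "))
  f <- writeRecordingFile(sp)
  rec <- readRecording(f)
  expect_equal(angles(rec), ang, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("write/read round-trip reproduces timestamps and angles", {
  rec <- generateUndulation(undulationParams(durationS = 3, seed = 11),
                            stage = "L3")
  f <- tempfile(fileext = ".txt")
  withr::defer(unlink(f))
  writeRecording(rec, f)
  rec2 <- readRecording(f, gait = gait(rec), stage = stage(rec))
  expect_equal(angles(rec2), angles(rec), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(timestamps(rec2), timestamps(rec), tolerance = 1e-5)
})

test_that("recording invariants are enforced by the class validity", {
  expect_error(PostureRecording(matrix(0.1, 3, 10), timestamps = c(0, 1, 1)),
               "strictly increasing")
  expect_error(PostureRecording(matrix(4, 2, 10)), "< pi")
  expect_error(PostureRecording(matrix(NA_real_, 2, 10)), "finite")
  expect_warning(PostureRecording(matrix(0.1, 10, 10),
                                  timestamps = seq(0, 9), samplingRate = 14),
                 "median frame interval")
})

test_that("discovery infers gait and stage from two folder levels", {
  root <- withr::local_tempdir()
  rec <- generateUndulation(undulationParams(durationS = 2, seed = 1))
  for (d in c("swimming/adult", "crawling/young L1", "crawling/L3"))
    dir.create(file.path(root, d), recursive = TRUE)
  writeRecording(rec, file.path(root, "swimming/adult/a1.txt"))
  writeRecording(rec, file.path(root, "swimming/adult/a2.txt"))
  writeRecording(rec, file.path(root, "crawling/young L1/y1.txt"))
  writeRecording(rec, file.path(root, "crawling/L3/l1.txt"))
  file.create(file.path(root, "swimming/adult/notes.csv"))
  d <- suppressMessages(discoverDataset(root))
  expect_equal(nrow(d), 4L)
  expect_equal(sum(d$gait == "swimming" & d$stage == "adult"), 2L)
  expect_equal(d$stage[d$gait == "crawling"], c("L3", "youngL1"))
  expect_false(any(grepl("csv$", d$path)))
})

test_that("unrecognized folders map to unknown and empty roots warn", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "hovering", "L9"), recursive = TRUE)
  writeRecording(generateUndulation(undulationParams(durationS = 2, seed = 2)),
                 file.path(root, "hovering", "L9", "x.txt"))
  msgs <- capture_messages(d <- discoverDataset(root))
  expect_match(msgs, "unrecognized gait", all = FALSE)
  expect_equal(d$gait, "unknown")
  expect_equal(d$stage, "unknown")
  empty <- withr::local_tempdir()
  expect_warning(d0 <- discoverDataset(empty), "no recognizable")
  expect_equal(nrow(d0), 0L)
})

test_that("stage aliases are case-insensitive", {
  expect_equal(wormPosture:::.normalizeStage(
    c("young L1", "L1_young", "YOUNGL1", "late l1", "Adults", "l2")),
    c("youngL1", "youngL1", "youngL1", "lateL1", "adult", "L2"))
  expect_equal(wormPosture:::.normalizeGait(c("Swim", "CRAWLING", "dive")),
               c("swimming", "crawling", "unknown"))
})
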