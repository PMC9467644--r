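# Reading TrackMate-style exports and the canonical round-trip format.

writeCsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("simple dialect parses track/frame/position columns", {
  path <- writeCsv(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "0,0,0,0", "0,1,1,0", "0,2,2,0"
  ))
  ts <- readTrackMateCsv(path, frameIntervalS = 2)
  expect_s4_class(ts, "TrajectorySet")
  expect_equal(nTracks(ts), 1L)
  expect_equal(nrow(spots(ts)), 3L)
  expect_equal(spots(ts)$x, c(0, 1, 2))
  expect_equal(nFrames(ts), 3L)
})

test_that("reader is insensitive to column order and extra columns", {
  path <- writeCsv(c(
    "QUALITY,POSITION_Y,FRAME,junk,POSITION_X,TRACK_ID",
    "3.2,4,0,zzz,3,7"
  ))
  ts <- readTrackMateCsv(path, frameIntervalS = 1)
  expect_equal(spots(ts)$x, 3)
  expect_equal(spots(ts)$y, 4)
  expect_equal(spots(ts)$track_id, 7L)
})

test_that("pixel positions are calibrated to micrometres", {
  path <- writeCsv(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "0,0,10,25"
  ))
  ts <- readTrackMateCsv(path, frameIntervalS = 1, pixelScale = 5)
  expect_equal(spots(ts)$x, 2)
  expect_equal(spots(ts)$y, 5)
})

test_that("trackmate7 sub-header rows are skipped, with autodetection", {
  lines <- c(
    "LABEL,ID,TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "Label,Spot ID,Track ID,Frame,X,Y",
    "Label,Spot ID,Track ID,Frame,(micron),(micron)",
    "ID1,1,0,0,1.5,2.5",
    "ID2,2,0,1,1.6,2.4"
  )
  path <- writeCsv(lines)
  auto <- readTrackMateCsv(path, frameIntervalS = 2)
  forced <- readTrackMateCsv(path, frameIntervalS = 2,
                             dialect = "trackmate7")
  expect_equal(spots(auto), spots(forced))
  expect_equal(nrow(spots(auto)), 2L)
  expect_equal(spots(auto)$x, c(1.5, 1.6))
})

test_that("unassigned-track spots are dropped and counted", {
  path <- writeCsv(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "0,0,1,1", "None,0,5,5", "-1,1,6,6", "0,1,1.5,1"
  ))
  expect_message(ts <- readTrackMateCsv(path, frameIntervalS = 1),
                 "dropped 2 spot")
  expect_equal(attr(ts, "nDroppedSpots"), 2L)
  expect_equal(nrow(spots(ts)), 2L)
})

test_that("format violations raise informative errors", {
  noCol <- writeCsv(c("TRACK_ID,FRAME,POSITION_X", "0,0,1"))
  expect_error(readTrackMateCsv(noCol, frameIntervalS = 1), "y")
  dup <- writeCsv(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "3,7,0,0", "3,7,1,1"
  ))
  expect_error(readTrackMateCsv(dup, frameIntervalS = 1),
               "duplicate.*track 3.*frame 7")
  empty <- writeCsv("TRACK_ID,FRAME,POSITION_X,POSITION_Y")
  expect_error(readTrackMateCsv(empty, frameIntervalS = 1), "empty input")
})

test_that("long internal frame gaps trigger a warning", {
  path <- writeCsv(c(
    "TRACK_ID,FRAME,POSITION_X,POSITION_Y",
    "0,0,0,0", "0,6,1,0"
  ))
  expect_warning(readTrackMateCsv(path, frameIntervalS = 1),
                 "frame gaps > 2")
})

test_that("canonical format round-trips exactly, including empty sets", {
  sc <- simulateCell(simulationConfig(nMito = 100, nFrames = 15, seed = 1))
  ts <- mito(cellRecord(sc))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCanonical(ts, path)
  back <- readCanonical(path)
  expect_identical(spots(back), spots(ts))
  expect_identical(nFrames(back), nFrames(ts))
  expect_identical(frameIntervalS(back), frameIntervalS(ts))
  expect_identical(organelleKind(back), organelleKind(ts))

  # repeated writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeCanonical(ts, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty set -> header-only file that still round-trips
  ets <- TrajectorySet(data.frame(track_id = integer(), frame = integer(),
                                  x = numeric(), y = numeric()),
                       frameIntervalS = 2, nFrames = 0L)
  pathE <- withr::local_tempfile(fileext = ".csv")
  writeCanonical(ets, pathE)
  backE <- readCanonical(pathE)
  expect_equal(nrow(spots(backE)), 0L)
  expect_identical(frameIntervalS(backE), 2)
})

test_that("TrajectorySet validity enforces the core invariants", {
  expect_error(
    TrajectorySet(data.frame(track_id = c(3L, 3L), frame = c(7L, 7L),
                             x = 0, y = 0), frameIntervalS = 1),
    "unique")
  expect_error(
    TrajectorySet(data.frame(track_id = 0L, frame = 0L, x = NaN, y = 0),
                  frameIntervalS = 1),
    "finite")
  expect_error(
    TrajectorySet(data.frame(track_id = 0L, frame = 5L, x = 0, y = 0),
                  frameIntervalS = 1, nFrames = 3L),
    "nFrames")
})

test_that("assembleCell validates frame compatibility and falls back to hull area", {
  m <- makeTs(0:1, c(0L, 0L), c(0, 1), c(0, 0), dt = 2, nFrames = 120L)
  chOk <- makeTs(0L, 0L, 5, 5, dt = 2, nFrames = 120L, kind = "chloroplast")
  chBad <- makeTs(0L, 0L, 5, 5, dt = 2, nFrames = 60L, kind = "chloroplast")
  expect_s4_class(assembleCell(m, chOk, cellAreaUm2 = 100), "CellRecord")
  expect_error(assembleCell(m, chBad, cellAreaUm2 = 100),
               "incompatible frame counts")

  # unit square corners -> hull area 1 um^2
  sq <- makeTs(0:3, rep(0L, 4), c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(cellArea(assembleCell(sq)), 1)
})
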