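# Reading TrackMate-style spot exports and the package's canonical format.
#
# TrackMate CSV exports changed shape across versions: older "simple"
# exports have one header row; version-7 exports insert extra descriptive
# sub-header rows (long names, units) between the header and the data. Both
# are supported, with autodetection by sniffing the first data row.

.COLUMN_ALIASES <- list(
  track_id = c("TRACK_ID", "TRACK ID", "TRACKID", "TRACK"),
  frame = c("FRAME", "T", "SPOT_FRAME"),
  x = c("POSITION_X", "X", "X_UM", "XUM"),
  y = c("POSITION_Y", "Y", "Y_UM", "YUM")
)

.normalizeHeader <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

.resolveColumns <- function(header) {
  norm <- .normalizeHeader(header)
  idx <- vapply(names(.COLUMN_ALIASES), function(field) {
    hit <- which(norm %in% .normalizeHeader(.COLUMN_ALIASES[[field]]))
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing)) {
    stop("required column(s) not found in header: ",
         paste(missing, collapse = ", "),
         " (accepted names include TRACK_ID, FRAME, POSITION_X, POSITION_Y)")
  }
  idx
}

#' Read a TrackMate-style spot table
#'
#' Parses a spot-statistics CSV as exported by TrackMate (or any table with
#' resolvable track id / frame / x / y columns) into a validated
#' [TrajectorySet-class]. Column order and extra columns are ignored; header
#' names are matched case-insensitively against common aliases.
#'
#' Spots whose track id is missing or unassigned (`NA`, empty, `"None"`,
#' negative id) were never linked into a trajectory and are dropped with a
#' message reporting the count.
#'
#' @param path path to the CSV file.
#' @param frameIntervalS seconds per frame. The acquisition interval is not
#'   stored in spot exports, so it must be supplied as metadata.
#' @param dialect `"auto"` (default), `"simple"` (one header row) or
#'   `"trackmate7"` (extra non-numeric sub-header rows after the header,
#'   which are skipped).
#' @param pixelScale pixels per µm if the file stores positions in pixels;
#'   positions are divided by this to give µm. `NULL` (default) means the
#'   file is already calibrated in µm. A typical calibration for the
#'   confocal data this package targets is 5 px/µm.
#' @param nFrames total frames observed; defaults to `max(frame) + 1`.
#' @param organelleKind `"mitochondrion"` (default) or `"chloroplast"`.
#' @param maxFrameGap tracks with internal gaps longer than this many
#'   frames trigger a warning (the default 2 matches the gap-closing
#'   setting used for tracking).
#' @return A [TrajectorySet-class]; the number of dropped unassigned spots
#'   is attached as attribute `"nDroppedSpots"`.
#' @seealso [writeCanonical()], [readCanonical()], [assembleCell()]
#' @export
readTrackMateCsv <- function(path, frameIntervalS,
                             dialect = c("auto", "simple", "trackmate7"),
                             pixelScale = NULL, nFrames = NULL,
                             organelleKind = "mitochondrion",
                             maxFrameGap = 2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("empty input: ", path, " has no data rows")
  idx <- .resolveColumns(names(raw))
  isSub <- function(row) {
    v <- suppressWarnings(as.numeric(row[idx["frame"]]))
    is.na(v)
  }
  if (dialect == "auto") {
    dialect <- if (isSub(raw[1L, ])) "trackmate7" else "simple"
  }
  if (dialect == "trackmate7") {
    while (nrow(raw) && isSub(raw[1L, ])) raw <- raw[-1L, , drop = FALSE]
    if (!nrow(raw)) stop("empty input: ", path,
                         " has only header rows, no data")
  }
  trackRaw <- raw[[idx["track_id"]]]
  unassigned <- is.na(trackRaw) | trackRaw == "" |
    toupper(trackRaw) %in% c("NONE", "NA") |
    suppressWarnings(as.numeric(trackRaw)) < 0
  unassigned[is.na(unassigned)] <- TRUE
  nDropped <- sum(unassigned)
  if (nDropped) {
    message("dropped ", nDropped, " spot(s) with unassigned track id")
    raw <- raw[!unassigned, , drop = FALSE]
  }
  if (!nrow(raw)) stop("empty input: no spots with assigned track ids")
  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[idx[field]]]))
    if (anyNA(v)) stop("non-numeric values in column for ", field)
    v
  }
  sp <- data.frame(track_id = as.integer(num("track_id")),
                   frame = as.integer(num("frame")),
                   x = num("x"), y = num("y"))
  if (anyDuplicated(sp[, c("track_id", "frame")])) {
    d <- sp[duplicated(sp[, c("track_id", "frame")]), , drop = FALSE][1L, ]
    stop("duplicate (track_id, frame) pair: track ", d$track_id,
         ", frame ", d$frame)
  }
  if (!is.null(pixelScale)) {
    stopifnot(pixelScale > 0)
    sp$x <- sp$x / pixelScale
    sp$y <- sp$y / pixelScale
  }
  ts <- TrajectorySet(sp, frameIntervalS = frameIntervalS,
                      nFrames = nFrames, organelleKind = organelleKind)
  gaps <- .tracksWithLongGaps(ts, maxFrameGap)
  if (length(gaps)) {
    warning(length(gaps), " track(s) have internal frame gaps > ",
            maxFrameGap, " frames (e.g. track ", gaps[1L], ")")
  }
  attr(ts, "nDroppedSpots") <- nDropped
  ts
}

# Track ids whose frame sequence has an internal gap exceeding maxFrameGap.
.tracksWithLongGaps <- function(ts, maxFrameGap) {
  sp <- ts@spots
  if (!nrow(sp)) return(integer())
  bad <- vapply(split(sp$frame, sp$track_id), function(fr) {
    fr <- sort(fr)
    length(fr) > 1L && any(diff(fr) > maxFrameGap + 1L)
  }, logical(1))
  as.integer(names(bad)[bad])
}

#' Write / read the canonical trajectory format
#'
#' The canonical format is a tidy CSV (`cell_id, organelle, track_id,
#' frame, x_um, y_um`) preceded by `#`-prefixed metadata lines carrying
#' `n_frames` and `frame_interval_s`, so a file round-trips to an identical
#' [TrajectorySet-class]. Positions are printed with 17 significant digits,
#' which reproduces doubles bit-exactly; repeated writes of the same object
#' are byte-identical.
#'
#' @param ts a [TrajectorySet-class].
#' @param path output (or input) file path.
#' @param cellId cell label written into the `cell_id` column.
#' @return `writeCanonical()`: `path`, invisibly. `readCanonical()`: a
#'   [TrajectorySet-class].
#' @export
writeCanonical <- function(ts, path, cellId = "cell") {
  stopifnot(is(ts, "TrajectorySet"))
  validObject(ts)
  sp <- ts@spots
  sp <- sp[order(sp$track_id, sp$frame), , drop = FALSE]
  lines <- c(
    "# canonical_trajectories v1",
    sprintf("# organelle=%s", ts@organelleKind),
    sprintf("# n_frames=%d", ts@nFrames),
    sprintf("# frame_interval_s=%.17g", ts@frameIntervalS),
    "cell_id,organelle,track_id,frame,x_um,y_um"
  )
  if (nrow(sp)) {
    lines <- c(lines, sprintf("%s,%s,%d,%d,%.17g,%.17g",
                              cellId, ts@organelleKind, sp$track_id,
                              sp$frame, sp$x, sp$y))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname writeCanonical
#' @export
readCanonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(hit)) stop("canonical file missing metadata line: ", key)
    sub(paste0("^# ", key, "="), "", hit[1L])
  }
  organelle <- getMeta("organelle")
  nFrames <- as.integer(getMeta("n_frames"))
  interval <- as.numeric(getMeta("frame_interval_s"))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  sp <- data.frame(track_id = df$track_id, frame = df$frame,
                   x = df$x_um, y = df$y_um)
  TrajectorySet(sp, frameIntervalS = interval, nFrames = nFrames,
                organelleKind = organelle)
}

#' Assemble a CellRecord from trajectory sets and metadata
#'
#' Combines a mitochondrial trajectory set, an optional chloroplast set
#' tracked in parallel, and per-cell metadata. If no cell area is supplied,
#' it is estimated as the area of the convex hull of all mitochondrial
#' positions over all frames — a documented fallback; prefer a measured
#' area (e.g. from the cell outline) when available, since the hull
#' underestimates concave cells.
#'
#' @param mito mitochondrial [TrajectorySet-class].
#' @param chloro chloroplast [TrajectorySet-class] or `NULL`.
#' @param cellId,genotype character labels.
#' @param cellAreaUm2 measured cell area in µm², or `NULL` for the
#'   convex-hull fallback.
#' @param pixelScale pixels per µm of the source images (default 5).
#' @return A validated [CellRecord-class].
#' @examples
#' sq <- TrajectorySet(
#'   data.frame(track_id = 0:3, frame = 0L,
#'              x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
#'   frameIntervalS = 2
#' )
#' cellArea(assembleCell(sq, cellId = "c1", genotype = "wt"))  # 1 um^2
#' @export
assembleCell <- function(mito, chloro = NULL, cellId = "cell",
                         genotype = "unknown", cellAreaUm2 = NULL,
                         pixelScale = 5) {
  stopifnot(is(mito, "TrajectorySet"))
  if (!is.null(chloro)) {
    if (chloro@nFrames != mito@nFrames) {
      stop("incompatible frame counts: mito has ", mito@nFrames,
           " frames, chloro has ", chloro@nFrames)
    }
    if (!isTRUE(all.equal(chloro@frameIntervalS, mito@frameIntervalS))) {
      stop("incompatible frame intervals between mito and chloro sets")
    }
  }
  if (is.null(cellAreaUm2)) {
    cellAreaUm2 <- .convexHullArea(as.matrix(mito@spots[, c("x", "y")]))
  }
  CellRecord(cellId = cellId, genotype = genotype, mito = mito,
             chloro = chloro, cellAreaUm2 = cellAreaUm2,
             pixelScale = pixelScale)
}
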