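# Per-cell physical summary statistics: speed, inter-mitochondrial
# spacing, and pairwise co-localization time.

#' Per-track mean speeds
#'
#' Speed is distance moved per frame per trajectory: for each track, the
#' Euclidean displacement between consecutive spots divided by the frame
#' gap between them, averaged over the track's steps. Steps across a
#' gap-closed segment (spot at frame f, next spot at frame f + g, g > 1)
#' divide the displacement by g, treating the gap as continuous motion —
#' the same semantics the gap-closing tracker assumes. Tracks with a single
#' spot contribute no speed and are excluded (their count is attached as
#' attribute `"nSingleSpotTracks"`).
#'
#' @param ts a [TrajectorySet-class].
#' @return Named numeric vector of per-track mean speeds (µm/frame), names
#'   are track ids.
#' @examples
#' ts <- TrajectorySet(data.frame(track_id = 0L, frame = 0:1,
#'                                x = c(0, 3), y = c(0, 4)),
#'                     frameIntervalS = 2)
#' trackSpeeds(ts)  # 5 um/frame
#' @export
trackSpeeds <- function(ts) {
  stopifnot(is(ts, "TrajectorySet"))
  sp <- ts@spots
  if (!nrow(sp)) {
    out <- numeric()
    attr(out, "nSingleSpotTracks") <- 0L
    return(out)
  }
  byTrack <- split(sp, sp$track_id)
  speeds <- vapply(byTrack, function(tr) {
    if (nrow(tr) < 2L) return(NA_real_)
    tr <- tr[order(tr$frame), , drop = FALSE]
    dg <- diff(tr$frame)
    stepDist <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    mean(stepDist / dg)
  }, numeric(1))
  nSingle <- sum(is.na(speeds))
  out <- speeds[!is.na(speeds)]
  attr(out, "nSingleSpotTracks") <- nSingle
  out
}

#' Mean inter-mitochondrial (nearest-neighbour) distance
#'
#' In each frame with at least two spots, every present mitochondrion is
#' paired with its nearest present neighbour; those minimum distances are
#' averaged within the frame, and the per-frame means are averaged over
#' frames. Averaging within frames first keeps crowded frames from
#' dominating the cell statistic. Frames with fewer than two spots are
#' skipped; if every frame is skipped the statistic is undefined (`NA`
#' with a warning).
#'
#' @param ts a [TrajectorySet-class].
#' @return A list: `meanUm` (the cell statistic, µm) and `perFrame`
#'   (data.frame of frame, n present, mean nearest-neighbour distance).
#' @export
interMitoDistance <- function(ts) {
  stopifnot(is(ts, "TrajectorySet"))
  frames <- .splitByFrame(ts@spots)
  rows <- lapply(frames, function(fr) {
    if (nrow(fr) < 2L) return(NULL)
    d <- as.matrix(stats::dist(fr[, c("x", "y")]))
    diag(d) <- Inf
    data.frame(frame = fr$frame[1L], n = nrow(fr),
               mean_nn_um = mean(apply(d, 1L, min)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("inter-mitochondrial distance undefined: ",
            "no frame has two concurrent spots")
    return(list(meanUm = NA_real_,
                perFrame = data.frame(frame = integer(), n = integer(),
                                      mean_nn_um = numeric())))
  }
  perFrame <- do.call(rbind, rows)
  rownames(perFrame) <- NULL
  list(meanUm = mean(perFrame$mean_nn_um), perFrame = perFrame)
}

#' Pairwise co-localization time
#'
#' For every unordered pair of tracks, counts the frames in which both are
#' present and within `thresholdUm` (closed comparison, `<=`) of each
#' other. Two cell-level aggregates are returned: the headline
#' `meanPositiveFrames`, the mean count over pairs that ever co-localize,
#' and `meanAllPairsFrames`, the mean over all `choose(nTracks, 2)` pairs
#' (most of which never meet). If no pair ever co-localizes both means are
#' 0 and `zeroPairs` is `TRUE`.
#'
#' @param ts a [TrajectorySet-class].
#' @param thresholdUm distance threshold in µm; the default 1.6 µm is the
#'   characteristic close-association distance, just over one
#'   mitochondrion's length.
#' @param window optional `c(from, to)` frame window (inclusive).
#' @return A list: `pairs` (data.frame track_i, track_j, n_frames for
#'   co-localizing pairs), `meanPositiveFrames`, `meanAllPairsFrames`,
#'   `nPairsPositive`, `nPairsTotal`, `zeroPairs`.
#' @export
colocTime <- function(ts, thresholdUm = 1.6, window = NULL) {
  stopifnot(is(ts, "TrajectorySet"))
  sp <- ts@spots
  if (!is.null(window)) {
    sp <- sp[sp$frame >= window[1] & sp$frame <= window[2], , drop = FALSE]
  }
  nt <- length(unique(sp$track_id))
  if (nt < 2L) stop("co-localization time needs at least 2 tracks")
  pairs <- .pairContactCounts(ts, thresholdUm, window)
  nPairsTotal <- choose(nt, 2)
  zero <- nrow(pairs) == 0L
  list(
    pairs = pairs,
    meanPositiveFrames = if (zero) 0 else mean(pairs$n_frames),
    meanAllPairsFrames = if (zero) 0 else sum(pairs$n_frames) / nPairsTotal,
    nPairsPositive = nrow(pairs),
    nPairsTotal = nPairsTotal,
    zeroPairs = zero
  )
}

#' Per-cell physical summary
#'
#' One row of physical statistics for one trajectory set over one window:
#' mean and median of per-track speeds, mean inter-mitochondrial
#' nearest-neighbour distance, and co-localization time (both aggregates).
#'
#' @param ts a [TrajectorySet-class] (already windowed if required; see
#'   [windowTrajectories()]).
#' @param thresholdUm co-localization threshold, µm (default 1.6).
#' @return One-row data.frame with columns `mean_speed_um_per_frame`,
#'   `median_speed_um_per_frame`, `mean_intermito_distance_um`,
#'   `mean_coloc_time_frames` (positive-pair mean),
#'   `mean_coloc_time_all_pairs`, `n_tracks`, `window_frames`.
#' @export
physicalSummary <- function(ts, thresholdUm = 1.6) {
  sp <- ts@spots
  speeds <- trackSpeeds(ts)
  nnd <- interMitoDistance(ts)
  ct <- if (length(unique(sp$track_id)) >= 2L) {
    colocTime(ts, thresholdUm)
  } else {
    list(meanPositiveFrames = NA_real_, meanAllPairsFrames = NA_real_)
  }
  wf <- if (nrow(sp)) max(sp$frame) - min(sp$frame) + 1L else 0L
  data.frame(
    mean_speed_um_per_frame = if (length(speeds)) mean(speeds) else NA_real_,
    median_speed_um_per_frame =
      if (length(speeds)) stats::median(speeds) else NA_real_,
    mean_intermito_distance_um = nnd$meanUm,
    mean_coloc_time_frames = ct$meanPositiveFrames,
    mean_coloc_time_all_pairs = ct$meanAllPairsFrames,
    n_tracks = length(unique(sp$track_id)),
    window_frames = wf
  )
}
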