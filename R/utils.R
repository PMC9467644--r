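# Internal geometry/bookkeeping helpers shared across modules.

# Subset a TrajectorySet to frames in [from, to] (inclusive), keeping
# nFrames/interval metadata intact so windows remain comparable.
#' Restrict a trajectory set to a frame window
#'
#' Returns a [TrajectorySet-class] containing only spots with frame index in
#' `[from, to]`. `nFrames` and `frameIntervalS` are preserved so statistics
#' over different windows of the same video stay comparable.
#'
#' @param ts a [TrajectorySet-class].
#' @param from,to inclusive frame bounds (0-based).
#' @return A [TrajectorySet-class].
#' @export
windowTrajectories <- function(ts, from, to) {
  stopifnot(is(ts, "TrajectorySet"))
  sp <- ts@spots
  sp <- sp[sp$frame >= from & sp$frame <= to, , drop = FALSE]
  rownames(sp) <- NULL
  new("TrajectorySet", spots = sp, nFrames = ts@nFrames,
      frameIntervalS = ts@frameIntervalS,
      organelleKind = ts@organelleKind)
}

# Split spots by frame; returns a named list of data.frames.
.splitByFrame <- function(sp) {
  if (!nrow(sp)) return(list())
  split(sp, sp$frame)
}

# Count, per unordered track pair, the frames in which both tracks are
# present and within thresholdUm of each other. This kernel backs both the
# co-localization time statistic and encounter-network construction, which
# keeps the two definitionally consistent (an edge exists iff the pair's
# count is positive).
.pairContactCounts <- function(ts, thresholdUm, window = NULL) {
  sp <- ts@spots
  if (!is.null(window)) {
    sp <- sp[sp$frame >= window[1] & sp$frame <= window[2], , drop = FALSE]
  }
  empty <- data.frame(track_i = integer(), track_j = integer(),
                      n_frames = integer())
  if (!nrow(sp)) return(empty)
  frames <- .splitByFrame(sp)
  pieces <- lapply(frames, function(fr) {
    n <- nrow(fr)
    if (n < 2L) return(NULL)
    d <- as.matrix(stats::dist(fr[, c("x", "y")]))
    hit <- which(d <= thresholdUm & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    a <- fr$track_id[hit[, 1L]]
    b <- fr$track_id[hit[, 2L]]
    cbind(pmin(a, b), pmax(a, b))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(empty)
  contacts <- do.call(rbind, pieces)
  key <- paste(contacts[, 1L], contacts[, 2L], sep = "|")
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  out <- data.frame(track_i = as.integer(ij[, 1L]),
                    track_j = as.integer(ij[, 2L]),
                    n_frames = as.integer(tab))
  out <- out[order(out$track_i, out$track_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shoelace polygon area of the convex hull of a two-column point matrix.
.convexHullArea <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) {
    stop("need at least 3 distinct positions to estimate area by convex hull")
  }
  h <- grDevices::chull(xy)
  px <- xy[h, 1L]; py <- xy[h, 2L]
  abs(sum(px * c(py[-1L], py[1L]) - c(px[-1L], px[1L]) * py)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
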