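# Time-accumulating encounter ("social") networks.
#
# Nodes are mitochondrial trajectories; an edge records at least one close
# approach (distance <= threshold) during the observation window. Because
# edges only ever accumulate, networks over nested windows are nested.

#' Build an encounter network
#'
#' Nodes are all tracks with at least one spot in the window; an edge
#' joins tracks i and j iff they were simultaneously present and within
#' `thresholdUm` of each other in at least one frame of the window. The
#' number of such frames is kept as the `n_frames` edge annotation, but the
#' network statistics treat edges as binary: a sustained contact of k
#' frames is one edge, not k.
#'
#' @param ts mitochondrial [TrajectorySet-class].
#' @param thresholdUm encounter distance in µm; the default 1.6 µm defines
#'   a characteristic close association (just over one mitochondrion's
#'   length). Lower thresholds yield fewer encounters.
#' @param window `c(from, to)` inclusive frame window; defaults to the
#'   whole video.
#' @return An [EncounterNetwork-class].
#' @examples
#' ts <- TrajectorySet(data.frame(track_id = c(0, 1, 0, 1),
#'                                frame = c(0, 0, 1, 1),
#'                                x = c(0, 5, 0, 1), y = 0),
#'                     frameIntervalS = 2)
#' buildNetwork(ts)  # 2 nodes, 1 edge (they touch in frame 1)
#' @export
buildNetwork <- function(ts, thresholdUm = 1.6, window = NULL) {
  stopifnot(is(ts, "TrajectorySet"))
  if (is.null(window)) {
    window <- c(0L, max(ts@nFrames - 1L, 0L))
  }
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sp <- ts@spots
  inWin <- sp$frame >= window[1] & sp$frame <= window[2]
  nodes <- sort(unique(sp$track_id[inWin]))
  pc <- .pairContactCounts(ts, thresholdUm, window)
  edges <- data.frame(from = pc$track_i, to = pc$track_j,
                      n_frames = pc$n_frames)
  EncounterNetwork(nodes = nodes, edges = edges, thresholdUm = thresholdUm,
                   windowStartFrame = window[1], windowEndFrame = window[2])
}

#' Series of accumulating networks at checkpoints
#'
#' Builds the encounter network over `[0, cp]` for each checkpoint frame
#' `cp`. Because encounters accumulate, node and edge sets are nested
#' across checkpoints. The default checkpoints expose the quarter, half,
#' three-quarter and full observation window.
#'
#' @param ts mitochondrial [TrajectorySet-class].
#' @param thresholdUm encounter distance in µm (default 1.6).
#' @param checkpoints ascending frame indices; default
#'   `round(nFrames * c(1, 2, 3, 4) / 4) - 1`.
#' @return Named list of [EncounterNetwork-class], names are checkpoint
#'   frames.
#' @export
networkSeries <- function(ts, thresholdUm = 1.6, checkpoints = NULL) {
  stopifnot(is(ts, "TrajectorySet"))
  if (is.null(checkpoints)) {
    checkpoints <- unique(pmax(round(ts@nFrames * (1:4) / 4) - 1, 0))
  }
  stopifnot(!is.unsorted(checkpoints, strictly = TRUE))
  nets <- lapply(checkpoints, function(cp) {
    buildNetwork(ts, thresholdUm, window = c(0L, as.integer(cp)))
  })
  names(nets) <- as.character(checkpoints)
  nets
}

#' Convert an EncounterNetwork to an igraph graph
#'
#' Vertices are named by track id; the per-edge encounter frame count is
#' stored as edge attribute `n_frames` (not `weight`, so igraph algorithms
#' stay unweighted, matching the binary-edge convention of the network
#' statistics).
#'
#' @param en an [EncounterNetwork-class].
#' @return An `igraph` undirected graph.
#' @export
asIgraph <- function(en) {
  stopifnot(is(en, "EncounterNetwork"))
  vertices <- data.frame(name = as.character(en@nodes))
  if (nrow(en@edges)) {
    d <- data.frame(from = as.character(en@edges$from),
                    to = as.character(en@edges$to),
                    n_frames = en@edges$n_frames)
    igraph::graph_from_data_frame(d, directed = FALSE, vertices = vertices)
  } else {
    igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = vertices)
  }
}

#' Export an encounter network
#'
#' Writes either a plain edge-list text file (`node_i node_j weight`, the
#' weight being the encounter frame count) or GraphML for use in external
#' graph tools.
#'
#' @param en an [EncounterNetwork-class].
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(en, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    ed <- en@edges
    lines <- c("# node_i node_j weight",
               sprintf("%d %d %d", ed$from, ed$to, ed$n_frames))
    writeLines(lines, path)
  } else {
    igraph::write_graph(asIgraph(en), path, format = "graphml")
  }
  invisible(path)
}
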