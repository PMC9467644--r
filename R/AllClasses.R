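#' @import methods
NULL

setClassUnion("TrajectorySetOrNULL", "NULL")

#' TrajectorySet: tracked organelle positions for one cell
#'
#' Container for all spots of one cell's tracked organelles. Each spot is one
#' detection: a trajectory (track) identifier, a 0-based frame index, and a
#' position in micrometres. Positions are always stored calibrated (µm);
#' conversion from pixels happens at read time.
#'
#' @slot spots data.frame with columns `track_id` (integer), `frame`
#'   (integer, 0-based), `x`, `y` (numeric, µm).
#' @slot nFrames integer, total number of frames observed (all spot frames
#'   are `< nFrames`).
#' @slot frameIntervalS numeric, seconds elapsed between consecutive frames.
#' @slot organelleKind `"mitochondrion"` or `"chloroplast"`.
#'
#' @name TrajectorySet-class
#' @aliases TrajectorySet-class
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(
    spots = "data.frame",
    nFrames = "integer",
    frameIntervalS = "numeric",
    organelleKind = "character"
  )
)

setValidity("TrajectorySet", function(object) {
  msg <- character()
  sp <- object@spots
  req <- c("track_id", "frame", "x", "y")
  if (!all(req %in% names(sp))) {
    return(paste0("spots must have columns ", paste(req, collapse = ", ")))
  }
  if (!is.numeric(sp$x) || !is.numeric(sp$y)) {
    msg <- c(msg, "x and y must be numeric")
  } else if (nrow(sp) && !all(is.finite(sp$x) & is.finite(sp$y))) {
    msg <- c(msg, "x and y must be finite")
  }
  if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
      object@nFrames < 0L) {
    msg <- c(msg, "nFrames must be a single non-negative integer")
  }
  if (nrow(sp)) {
    if (any(sp$frame < 0L)) msg <- c(msg, "frame indices must be >= 0")
    if (any(sp$frame >= object@nFrames)) {
      msg <- c(msg, "every spot frame must be < nFrames")
    }
    if (anyDuplicated(sp[, c("track_id", "frame")])) {
      msg <- c(msg, "(track_id, frame) pairs must be unique")
    }
  }
  if (length(object@frameIntervalS) != 1L ||
      !is.finite(object@frameIntervalS) || object@frameIntervalS <= 0) {
    msg <- c(msg, "frameIntervalS must be a single positive number")
  }
  if (!object@organelleKind %in% c("mitochondrion", "chloroplast")) {
    msg <- c(msg, "organelleKind must be 'mitochondrion' or 'chloroplast'")
  }
  if (length(msg)) msg else TRUE
})

setIs("TrajectorySet", "TrajectorySetOrNULL")

#' Construct a TrajectorySet
#'
#' @param spots data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (positions in µm, frames 0-based).
#' @param frameIntervalS seconds per frame. The acquisition interval is not
#'   recoverable from a spot table, so it is required metadata.
#' @param nFrames total frames observed; defaults to `max(frame) + 1`.
#' @param organelleKind `"mitochondrion"` (default) or `"chloroplast"`.
#'
#' @return A validated [TrajectorySet-class] object.
#' @examples
#' ts <- TrajectorySet(
#'   data.frame(track_id = 0L, frame = 0:2, x = c(0, 1, 2), y = 0),
#'   frameIntervalS = 2
#' )
#' nTracks(ts)
#' @export
TrajectorySet <- function(spots, frameIntervalS, nFrames = NULL,
                          organelleKind = "mitochondrion") {
  spots <- as.data.frame(spots)
  if (nrow(spots)) {
    spots$track_id <- as.integer(spots$track_id)
    spots$frame <- as.integer(spots$frame)
    spots$x <- as.numeric(spots$x)
    spots$y <- as.numeric(spots$y)
    spots <- spots[order(spots$track_id, spots$frame),
                   c("track_id", "frame", "x", "y"), drop = FALSE]
    rownames(spots) <- NULL
  } else {
    spots <- data.frame(track_id = integer(), frame = integer(),
                        x = numeric(), y = numeric())
  }
  if (is.null(nFrames)) {
    nFrames <- if (nrow(spots)) max(spots$frame) + 1L else 0L
  }
  new("TrajectorySet", spots = spots, nFrames = as.integer(nFrames),
      frameIntervalS = as.numeric(frameIntervalS),
      organelleKind = organelleKind)
}

#' CellRecord: one cell's trajectories plus metadata
#'
#' Bundles the mitochondrial trajectory set of one cell, an optional
#' chloroplast trajectory set recorded in parallel, and the per-cell
#' metadata needed downstream: genotype label, cell area estimate and the
#' pixel calibration the source images used.
#'
#' @slot cellId character identifier, unique within a cohort.
#' @slot genotype character genotype/group label (e.g. `"mtGFP"`,
#'   `"msh1"`, `"friendly"`).
#' @slot mito [TrajectorySet-class] of mitochondria.
#' @slot chloro [TrajectorySet-class] of chloroplasts, or `NULL`.
#' @slot cellAreaUm2 numeric, cell area A in µm² (used by the enrichment
#'   statistic).
#' @slot pixelScale numeric, pixels per µm of the source images.
#'
#' @name CellRecord-class
#' @exportClass CellRecord
setClass("CellRecord",
  representation(
    cellId = "character",
    genotype = "character",
    mito = "TrajectorySet",
    chloro = "TrajectorySetOrNULL",
    cellAreaUm2 = "numeric",
    pixelScale = "numeric"
  )
)

setValidity("CellRecord", function(object) {
  msg <- character()
  if (!is.finite(object@cellAreaUm2) || object@cellAreaUm2 <= 0) {
    msg <- c(msg, "cellAreaUm2 must be positive")
  }
  if (!is.finite(object@pixelScale) || object@pixelScale <= 0) {
    msg <- c(msg, "pixelScale must be positive")
  }
  if (!is.null(object@chloro)) {
    if (object@chloro@nFrames != object@mito@nFrames) {
      msg <- c(msg, "mito and chloro must share nFrames")
    }
    if (!isTRUE(all.equal(object@chloro@frameIntervalS,
                          object@mito@frameIntervalS))) {
      msg <- c(msg, "mito and chloro must share frameIntervalS")
    }
    if (object@chloro@organelleKind != "chloroplast") {
      msg <- c(msg, "chloro slot must contain a chloroplast TrajectorySet")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellRecord
#'
#' Thin constructor; see [assembleCell()] for the user-facing assembly path
#' with the convex-hull area fallback.
#'
#' @param cellId,genotype character labels.
#' @param mito mitochondrial [TrajectorySet-class].
#' @param chloro chloroplast [TrajectorySet-class] or `NULL`.
#' @param cellAreaUm2 cell area in µm².
#' @param pixelScale pixels per µm (default 5, the calibration used for the
#'   hypocotyl imaging this package targets).
#' @return A validated [CellRecord-class].
#' @export
CellRecord <- function(cellId, genotype, mito, chloro = NULL,
                       cellAreaUm2, pixelScale = 5) {
  new("CellRecord", cellId = as.character(cellId),
      genotype = as.character(genotype), mito = mito, chloro = chloro,
      cellAreaUm2 = as.numeric(cellAreaUm2),
      pixelScale = as.numeric(pixelScale))
}

#' EncounterNetwork: accumulated close-approach graph of one cell
#'
#' Undirected graph over mitochondrial trajectory identifiers. An edge
#' records that the two trajectories came within the encounter threshold of
#' each other in at least one frame of the observation window; the
#' `n_frames` edge annotation counts those frames. Networks only accumulate:
#' for nested windows at a fixed threshold the edge sets are nested.
#'
#' @slot nodes integer vector of track ids with at least one spot in the
#'   window.
#' @slot edges data.frame with columns `from`, `to` (track ids, `from < to`)
#'   and `n_frames` (number of frames within threshold).
#' @slot thresholdUm numeric encounter distance threshold (µm).
#' @slot windowStartFrame,windowEndFrame integer frame bounds (inclusive).
#'
#' @name EncounterNetwork-class
#' @exportClass EncounterNetwork
setClass("EncounterNetwork",
  representation(
    nodes = "integer",
    edges = "data.frame",
    thresholdUm = "numeric",
    windowStartFrame = "integer",
    windowEndFrame = "integer"
  )
)

setValidity("EncounterNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("from", "to", "n_frames") %in% names(ed))) {
    return("edges must have columns from, to, n_frames")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (nrow(ed)) {
    if (any(ed$from >= ed$to)) msg <- c(msg, "edges must satisfy from < to")
    if (!all(c(ed$from, ed$to) %in% object@nodes)) {
      msg <- c(msg, "edge endpoints must be in the node set")
    }
    if (anyDuplicated(ed[, c("from", "to")])) {
      msg <- c(msg, "duplicate edges are not allowed")
    }
    if (any(ed$n_frames < 1L)) msg <- c(msg, "edge n_frames must be >= 1")
  }
  if (object@thresholdUm <= 0) msg <- c(msg, "thresholdUm must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an EncounterNetwork directly
#'
#' Mostly used internally by [buildNetwork()]; exported so that graphs with
#' known structure (paths, stars, complete graphs) can be fed to the network
#' statistics.
#'
#' @param nodes integer vector of node (track) identifiers.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `n_frames` (defaults to 1 per edge).
#' @param thresholdUm encounter threshold annotation (µm), default 1.6.
#' @param windowStartFrame,windowEndFrame window annotation (frames).
#' @return An [EncounterNetwork-class].
#' @examples
#' path3 <- EncounterNetwork(1:3, data.frame(from = 1:2, to = 2:3))
#' networkEfficiency(path3)  # 5/6
#' @export
EncounterNetwork <- function(nodes, edges = NULL, thresholdUm = 1.6,
                             windowStartFrame = 0L, windowEndFrame = 0L) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = integer(), to = integer(),
                        n_frames = integer())
  } else {
    edges <- as.data.frame(edges)
    if (is.null(edges$n_frames)) edges$n_frames <- 1L
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- as.integer(a)
    edges$to <- as.integer(b)
    edges$n_frames <- as.integer(edges$n_frames)
    edges <- edges[order(edges$from, edges$to),
                   c("from", "to", "n_frames"), drop = FALSE]
    rownames(edges) <- NULL
  }
  new("EncounterNetwork", nodes = sort(as.integer(nodes)), edges = edges,
      thresholdUm = as.numeric(thresholdUm),
      windowStartFrame = as.integer(windowStartFrame),
      windowEndFrame = as.integer(windowEndFrame))
}

#' SimulationConfig: parameterization of the synthetic motion model
#'
#' Full description of one simulated cell: population sizes, domain, frame
#' structure, the static/diffusive/ballistic motion mixture, motility
#' parameters, optional sticking/clustering, and the random seed.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nMito = "integer",
    nChloro = "integer",
    domainUm = "numeric",
    nFrames = "integer",
    frameIntervalS = "numeric",
    fractions = "numeric",
    diffusionCoeff = "numeric",
    ballisticSpeed = "numeric",
    directionPersistence = "numeric",
    clustering = "list",
    chloroRadiusUm = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- object@fractions
  if (length(fr) != 3L ||
      !identical(names(fr), c("static", "diffusive", "ballistic"))) {
    msg <- c(msg, "fractions must be named (static, diffusive, ballistic)")
  } else {
    if (any(fr < 0)) msg <- c(msg, "fractions must be non-negative")
    if (abs(sum(fr) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  }
  if (length(object@domainUm) != 2L || any(object@domainUm <= 0)) {
    msg <- c(msg, "domainUm must be a positive (width, height)")
  }
  if (object@nMito < 0L || object@nChloro < 0L) {
    msg <- c(msg, "population sizes must be non-negative")
  }
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@frameIntervalS <= 0) {
    msg <- c(msg, "frameIntervalS must be positive")
  }
  if (object@diffusionCoeff < 0 || object@ballisticSpeed < 0) {
    msg <- c(msg, "motility rates must be non-negative")
  }
  if (object@directionPersistence < 0 || object@directionPersistence > 1) {
    msg <- c(msg, "directionPersistence must be in [0, 1]")
  }
  cl <- object@clustering
  need <- c("attractionRadiusUm", "stickingProb", "unstickingProb",
            "memberJitterCoeff")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, paste0("clustering must have fields ",
                         paste(need, collapse = ", ")))
  } else if (any(unlist(cl[need]) < 0) ||
             cl$stickingProb > 1 || cl$unstickingProb > 1) {
    msg <- c(msg, "clustering probabilities must be in [0, 1], rates >= 0")
  }
  if (object@chloroRadiusUm <= 0) {
    msg <- c(msg, "chloroRadiusUm must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe a plausible hypocotyl cell: ~100 mitochondria in a
#' 60x60 µm quasi-2D domain, 120 frames spanning a 233 s observation window
#' (frame interval 233/120 s), a mixture of static (30%), diffusive (50%)
#' and ballistic (20%) movers. Motility defaults (D = 0.05 µm²/s, v = 0.4
#' µm/s, heading persistence 0.9 per frame) are plausible for cytoplasmic
#' organelle transport; see the package vignette for the reasoning.
#' Clustering (sticking) is off by default (`stickingProb = 0`).
#'
#' @param nMito,nChloro population sizes.
#' @param domainUm numeric length-2, domain width and height in µm.
#' @param nFrames number of frames.
#' @param frameIntervalS seconds per frame.
#' @param fractions numeric length-3 `(static, diffusive, ballistic)`,
#'   must sum to 1.
#' @param diffusionCoeff diffusion coefficient D of diffusive movers, µm²/s.
#' @param ballisticSpeed speed v of ballistic movers, µm/s.
#' @param directionPersistence per-frame probability a ballistic mover keeps
#'   its heading.
#' @param clustering list with `attractionRadiusUm`, `stickingProb`,
#'   `unstickingProb`, `memberJitterCoeff`; pairs closer than the radius
#'   stick with `stickingProb` per frame (the cluster then moves jointly)
#'   and members release with `unstickingProb` per frame. While stuck,
#'   each member also takes an independent small Brownian step with
#'   diffusion coefficient `memberJitterCoeff` (µm²/s) on top of the
#'   shared cluster displacement, so clusters are dense milling
#'   aggregates rather than rigid bodies; set it to 0 for rigid
#'   co-movement. A partial list is merged into the defaults.
#' @param chloroRadiusUm chloroplast disc radius, µm (default 1.5, a
#'   typical chloroplast radius).
#' @param seed integer random seed.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nMito = 100, nChloro = 0,
                             domainUm = c(60, 60), nFrames = 120,
                             frameIntervalS = 233 / 120,
                             fractions = c(static = 0.3, diffusive = 0.5,
                                           ballistic = 0.2),
                             diffusionCoeff = 0.05, ballisticSpeed = 0.4,
                             directionPersistence = 0.9,
                             clustering = list(attractionRadiusUm = 1.6,
                                               stickingProb = 0,
                                               unstickingProb = 0.05,
                                               memberJitterCoeff = 0.01),
                             chloroRadiusUm = 1.5, seed = 1) {
  fractions <- as.numeric(fractions)
  names(fractions) <- c("static", "diffusive", "ballistic")
  # a partial clustering list is merged into the defaults
  clDefault <- list(attractionRadiusUm = 1.6, stickingProb = 0,
                    unstickingProb = 0.05, memberJitterCoeff = 0.01)
  clDefault[names(clustering)] <- clustering
  clustering <- clDefault
  new("SimulationConfig", nMito = as.integer(nMito),
      nChloro = as.integer(nChloro), domainUm = as.numeric(domainUm),
      nFrames = as.integer(nFrames),
      frameIntervalS = as.numeric(frameIntervalS), fractions = fractions,
      diffusionCoeff = as.numeric(diffusionCoeff),
      ballisticSpeed = as.numeric(ballisticSpeed),
      directionPersistence = as.numeric(directionPersistence),
      clustering = clustering, chloroRadiusUm = as.numeric(chloroRadiusUm),
      seed = as.integer(seed))
}

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SimulatedCell: a synthetic cell plus its ground truth
#'
#' Output of [simulateCell()]: the [CellRecord-class] that downstream
#' analysis sees, plus the ground truth the generator knows — the motion
#' class programmed for each track, the full per-frame cluster membership
#' history (when clustering is on), and chloroplast centres.
#'
#' @slot cell the [CellRecord-class].
#' @slot motionClass character vector (`"static"`, `"diffusive"`,
#'   `"ballistic"`) named by track id.
#' @slot clusterHistory integer matrix (frames x tracks) of cluster labels,
#'   or `NULL` when clustering is disabled. Two tracks sharing a label in a
#'   frame moved jointly in that frame.
#' @slot chloroCentres numeric matrix (nChloro x 2) of disc centres, or
#'   `NULL`.
#' @name SimulatedCell-class
#' @exportClass SimulatedCell
setClass("SimulatedCell",
  representation(
    cell = "CellRecord",
    motionClass = "character",
    clusterHistory = "matrixOrNULL",
    chloroCentres = "matrixOrNULL"
  )
)

setValidity("SimulatedCell", function(object) {
  ids <- unique(object@cell@mito@spots$track_id)
  if (!all(as.integer(names(object@motionClass)) %in% ids)) {
    return("ground-truth track ids must be a subset of the cell's tracks")
  }
  TRUE
})
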