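#' Accessors for ChondrioNet classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a [TrajectorySet-class], [CellRecord-class],
#'   [EncounterNetwork-class] or [SimulatedCell-class].
#' @name accessors
NULL

#' @rdname accessors
#' @return `spots()`: the spot data.frame (track_id, frame, x, y).
#' @export
setGeneric("spots", function(object) standardGeneric("spots"))

#' @rdname accessors
#' @export
setMethod("spots", "TrajectorySet", function(object) object@spots)

#' @rdname accessors
#' @return `nFrames()`: total frames observed.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectorySet", function(object) object@nFrames)

#' @rdname accessors
#' @return `frameIntervalS()`: seconds per frame.
#' @export
setGeneric("frameIntervalS",
           function(object) standardGeneric("frameIntervalS"))

#' @rdname accessors
#' @export
setMethod("frameIntervalS", "TrajectorySet",
          function(object) object@frameIntervalS)

#' @rdname accessors
#' @return `organelleKind()`: `"mitochondrion"` or `"chloroplast"`.
#' @export
setGeneric("organelleKind",
           function(object) standardGeneric("organelleKind"))

#' @rdname accessors
#' @export
setMethod("organelleKind", "TrajectorySet",
          function(object) object@organelleKind)

#' @rdname accessors
#' @return `trackIds()`: sorted unique track identifiers.
#' @export
setGeneric("trackIds", function(object) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setMethod("trackIds", "TrajectorySet",
          function(object) sort(unique(object@spots$track_id)))

#' @rdname accessors
#' @return `nTracks()`: number of distinct tracks.
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setMethod("nTracks", "TrajectorySet",
          function(object) length(unique(object@spots$track_id)))

#' @rdname accessors
#' @return `cellId()`, `genotype()`: cell metadata labels.
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setMethod("cellId", "CellRecord", function(object) object@cellId)

#' @rdname accessors
#' @export
setGeneric("genotype", function(object) standardGeneric("genotype"))

#' @rdname accessors
#' @export
setMethod("genotype", "CellRecord", function(object) object@genotype)

#' @rdname accessors
#' @return `mito()`, `chloro()`: the organelle trajectory sets.
#' @export
setGeneric("mito", function(object) standardGeneric("mito"))

#' @rdname accessors
#' @export
setMethod("mito", "CellRecord", function(object) object@mito)

#' @rdname accessors
#' @export
setGeneric("chloro", function(object) standardGeneric("chloro"))

#' @rdname accessors
#' @export
setMethod("chloro", "CellRecord", function(object) object@chloro)

#' @rdname accessors
#' @return `cellArea()`: cell area in µm².
#' @export
setGeneric("cellArea", function(object) standardGeneric("cellArea"))

#' @rdname accessors
#' @export
setMethod("cellArea", "CellRecord", function(object) object@cellAreaUm2)

#' @rdname accessors
#' @return `pixelScale()`: pixels per µm.
#' @export
setGeneric("pixelScale", function(object) standardGeneric("pixelScale"))

#' @rdname accessors
#' @export
setMethod("pixelScale", "CellRecord", function(object) object@pixelScale)

#' @rdname accessors
#' @return `networkNodes()`, `networkEdges()`: node vector and edge table.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setMethod("networkNodes", "EncounterNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("networkEdges", "EncounterNetwork", function(object) object@edges)

#' @rdname accessors
#' @return `thresholdUm()`: the encounter distance threshold (µm).
#' @export
setGeneric("thresholdUm", function(object) standardGeneric("thresholdUm"))

#' @rdname accessors
#' @export
setMethod("thresholdUm", "EncounterNetwork",
          function(object) object@thresholdUm)

#' @rdname accessors
#' @return `windowEndFrame()`: last frame (inclusive) of the window.
#' @export
setGeneric("windowEndFrame",
           function(object) standardGeneric("windowEndFrame"))

#' @rdname accessors
#' @export
setMethod("windowEndFrame", "EncounterNetwork",
          function(object) object@windowEndFrame)

#' @rdname accessors
#' @return `cellRecord()`: the [CellRecord-class] of a simulated cell.
#' @export
setGeneric("cellRecord", function(object) standardGeneric("cellRecord"))

#' @rdname accessors
#' @export
setMethod("cellRecord", "SimulatedCell", function(object) object@cell)

#' @rdname accessors
#' @return `motionClasses()`: programmed motion class per track.
#' @export
setGeneric("motionClasses", function(object) standardGeneric("motionClasses"))

#' @rdname accessors
#' @export
setMethod("motionClasses", "SimulatedCell",
          function(object) object@motionClass)

#' @rdname accessors
#' @return `clusterHistory()`: frames x tracks matrix of cluster labels, or
#'   `NULL`.
#' @export
setGeneric("clusterHistory",
           function(object) standardGeneric("clusterHistory"))

#' @rdname accessors
#' @export
setMethod("clusterHistory", "SimulatedCell",
          function(object) object@clusterHistory)

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf(
    "TrajectorySet: %d %s track(s), %d spot(s), %d frame(s) (dt = %.4g s)\n",
    nTracks(object), object@organelleKind, nrow(object@spots),
    object@nFrames, object@frameIntervalS))
})

setMethod("show", "CellRecord", function(object) {
  cat(sprintf("CellRecord '%s' [%s]\n", object@cellId, object@genotype))
  cat(sprintf("  area: %.1f um^2, pixel scale: %g px/um\n",
              object@cellAreaUm2, object@pixelScale))
  cat("  mito:   "); show(object@mito)
  if (!is.null(object@chloro)) {
    cat("  chloro: "); show(object@chloro)
  }
})

setMethod("show", "EncounterNetwork", function(object) {
  cat(sprintf(
    "EncounterNetwork: %d node(s), %d edge(s); threshold %.2f um, frames [%d, %d]\n",
    length(object@nodes), nrow(object@edges), object@thresholdUm,
    object@windowStartFrame, object@windowEndFrame))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d mito, %d chloro in %g x %g um; %d frames (dt = %.4g s)\n",
    object@nMito, object@nChloro, object@domainUm[1], object@domainUm[2],
    object@nFrames, object@frameIntervalS))
  cat(sprintf("  fractions: static %.2f / diffusive %.2f / ballistic %.2f\n",
              object@fractions[1], object@fractions[2], object@fractions[3]))
  cat(sprintf("  D = %g um^2/s, v = %g um/s, persistence = %g, seed = %d\n",
              object@diffusionCoeff, object@ballisticSpeed,
              object@directionPersistence, object@seed))
  if (object@clustering$stickingProb > 0) {
    cat(sprintf("  clustering: radius %g um, stick %g, unstick %g\n",
                object@clustering$attractionRadiusUm,
                object@clustering$stickingProb,
                object@clustering$unstickingProb))
  }
})

setMethod("show", "SimulatedCell", function(object) {
  cat("SimulatedCell with ground truth\n")
  show(object@cell)
})
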