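# The five summary statistics of an encounter network: mean degree, global
# efficiency, diameter, mean betweenness centrality and connected-component
# count. All are computed on the unweighted (binary-edge) graph.

.requireNodes <- function(en, n, what) {
  if (length(en@nodes) < n) {
    warning(what, " undefined: network has fewer than ", n, " node(s)")
    return(FALSE)
  }
  TRUE
}

#' Mean degree
#'
#' Number of immediate neighbours each node has, averaged over the number
#' of nodes. Tracks that never encountered anyone are isolated nodes and
#' count in the denominator by default; set `includeIsolated = FALSE` to
#' average over connected nodes only.
#'
#' @param en an [EncounterNetwork-class].
#' @param includeIsolated include degree-0 nodes in the average (default
#'   `TRUE`).
#' @return Mean degree (edges per node), or `NA` for an empty network.
#' @export
meanDegree <- function(en, includeIsolated = TRUE) {
  stopifnot(is(en, "EncounterNetwork"))
  if (!.requireNodes(en, 1L, "mean degree")) return(NA_real_)
  deg <- table(factor(c(en@edges$from, en@edges$to), levels = en@nodes))
  deg <- as.numeric(deg)
  if (!includeIsolated) {
    deg <- deg[deg > 0]
    if (!length(deg)) return(0)
  }
  mean(deg)
}

#' Global network efficiency
#'
#' The average over all ordered pairs of distinct nodes of the reciprocal
#' shortest-path length (in hops):
#' `E(G) = 1/(n(n-1)) * sum_{i != j} 1/d(i, j)`,
#' with `1/d = 0` for disconnected pairs. Efficiency is 1 exactly for a
#' complete graph and low when the network fragments.
#'
#' @param en an [EncounterNetwork-class].
#' @return Efficiency in `[0, 1]`, or `NA` when fewer than 2 nodes.
#' @export
networkEfficiency <- function(en) {
  stopifnot(is(en, "EncounterNetwork"))
  if (!.requireNodes(en, 2L, "efficiency")) return(NA_real_)
  d <- igraph::distances(asIgraph(en), weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0  # disconnected pairs and the diagonal
  diag(inv) <- 0
  n <- length(en@nodes)
  sum(inv) / (n * (n - 1))
}

#' Graph diameter (largest component)
#'
#' Longest shortest-path length (in edges) between any connected pair of
#' nodes. On a disconnected network the diameter is computed within the
#' largest connected component (ties broken towards the component
#' containing the smallest node id); report [nComponents()] alongside so
#' fragmentation is not hidden.
#'
#' @param en an [EncounterNetwork-class].
#' @return Diameter in edges, or `NA` for an edgeless network.
#' @export
networkDiameter <- function(en) {
  stopifnot(is(en, "EncounterNetwork"))
  if (!.requireNodes(en, 2L, "diameter")) return(NA_real_)
  if (!nrow(en@edges)) {
    warning("diameter undefined: network has no edges")
    return(NA_real_)
  }
  g <- asIgraph(en)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # tie-break: component holding the smallest node id
    first <- vapply(big, function(k) {
      min(as.integer(igraph::V(g)$name[comp$membership == k]))
    }, numeric(1))
    big <- big[which.min(first)]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.numeric(igraph::diameter(sub, unconnected = FALSE, weights = NA))
}

#' Mean betweenness centrality
#'
#' Betweenness of a node is the number of shortest paths between other
#' node pairs passing through it, with fractional credit when several
#' shortest paths tie; endpoints are excluded. The mean over nodes is
#' returned raw by default; `normalized = TRUE` divides each node's value
#' by `(n-1)(n-2)/2`, the number of pairs that could route through it.
#'
#' @param en an [EncounterNetwork-class].
#' @param normalized return the normalized mean (default `FALSE`).
#' @return Mean betweenness; 0 for networks with fewer than 3 nodes.
#' @export
meanBetweenness <- function(en, normalized = FALSE) {
  stopifnot(is(en, "EncounterNetwork"))
  n <- length(en@nodes)
  if (n < 3L) return(0)
  b <- igraph::betweenness(asIgraph(en), directed = FALSE, weights = NA)
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  mean(b)
}

#' Number of connected components
#'
#' Isolated nodes each count as one component.
#'
#' @param en an [EncounterNetwork-class].
#' @return Component count (0 for an empty network).
#' @export
nComponents <- function(en) {
  stopifnot(is(en, "EncounterNetwork"))
  if (!length(en@nodes)) return(0L)
  igraph::components(asIgraph(en))$no
}

#' Summarise an encounter network
#'
#' All five network statistics in one row. Statistics that are undefined
#' for the given network (efficiency with < 2 nodes, diameter of an
#' edgeless graph) are `NA` without warnings here, so cohort sweeps stay
#' quiet.
#'
#' @param en an [EncounterNetwork-class].
#' @param includeIsolated passed to [meanDegree()].
#' @return One-row data.frame: `window_end_frame`, `threshold_um`,
#'   `n_nodes`, `n_edges`, `mean_degree`, `efficiency`, `diameter`,
#'   `mean_betweenness`, `mean_betweenness_normalized`, `n_components`.
#' @export
networkSummary <- function(en, includeIsolated = TRUE) {
  stopifnot(is(en, "EncounterNetwork"))
  quiet <- function(expr) suppressWarnings(expr)
  data.frame(
    window_end_frame = en@windowEndFrame,
    threshold_um = en@thresholdUm,
    n_nodes = length(en@nodes),
    n_edges = nrow(en@edges),
    mean_degree = quiet(meanDegree(en, includeIsolated)),
    efficiency = quiet(networkEfficiency(en)),
    diameter = quiet(networkDiameter(en)),
    mean_betweenness = meanBetweenness(en),
    mean_betweenness_normalized = meanBetweenness(en, normalized = TRUE),
    n_components = nComponents(en)
  )
}

#' Summarise a series of networks
#'
#' One [networkSummary()] row per checkpoint network, stacked.
#'
#' @param series list of [EncounterNetwork-class] from [networkSeries()].
#' @param includeIsolated passed to [meanDegree()].
#' @return data.frame with one row per network (empty for an empty series).
#' @export
summarizeSeries <- function(series, includeIsolated = TRUE) {
  if (!length(series)) {
    return(networkSummary(EncounterNetwork(integer()))[0L, ])
  }
  out <- do.call(rbind, lapply(series, networkSummary,
                               includeIsolated = includeIsolated))
  rownames(out) <- NULL
  out
}
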