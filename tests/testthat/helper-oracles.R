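# Independent brute-force oracles. These deliberately re-derive every
# statistic by direct enumeration (pair-by-pair, frame-by-frame,
# Floyd-Warshall, BFS path counting) and never call the package's
# implementation paths or igraph.

# --- trajectory fixtures ---------------------------------------------------

makeTs <- function(track_id, frame, x, y, dt = 2, nFrames = NULL,
                   kind = "mitochondrion") {
  TrajectorySet(data.frame(track_id = track_id, frame = frame, x = x, y = y),
                frameIntervalS = dt, nFrames = nFrames, organelleKind = kind)
}

# random small cell: tracks present in all frames, positions uniform
randomTs <- function(nTracks, nFrames, domain = 20, dt = 2) {
  sp <- expand.grid(frame = 0:(nFrames - 1), track_id = 0:(nTracks - 1))
  sp$x <- stats::runif(nrow(sp), 0, domain)
  sp$y <- stats::runif(nrow(sp), 0, domain)
  makeTs(sp$track_id, sp$frame, sp$x, sp$y, dt = dt)
}

# --- physical-statistic oracles -------------------------------------------

bfSpeeds <- function(ts) {
  sp <- spots(ts)
  out <- numeric(0)
  for (id in sort(unique(sp$track_id))) {
    tr <- sp[sp$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    s <- numeric(0)
    for (k in 2:nrow(tr)) {
      d <- sqrt((tr$x[k] - tr$x[k - 1])^2 + (tr$y[k] - tr$y[k - 1])^2)
      s <- c(s, d / (tr$frame[k] - tr$frame[k - 1]))
    }
    out[as.character(id)] <- mean(s)
  }
  out
}

bfNNDistance <- function(ts) {
  sp <- spots(ts)
  frameMeans <- numeric(0)
  for (f in sort(unique(sp$frame))) {
    fr <- sp[sp$frame == f, ]
    if (nrow(fr) < 2) next
    mins <- numeric(nrow(fr))
    for (i in seq_len(nrow(fr))) {
      dd <- Inf
      for (j in seq_len(nrow(fr))) {
        if (i == j) next
        dd <- min(dd, sqrt((fr$x[i] - fr$x[j])^2 + (fr$y[i] - fr$y[j])^2))
      }
      mins[i] <- dd
    }
    frameMeans <- c(frameMeans, mean(mins))
  }
  if (!length(frameMeans)) NA_real_ else mean(frameMeans)
}

bfPairContacts <- function(ts, threshold, window = NULL) {
  sp <- spots(ts)
  if (!is.null(window)) {
    sp <- sp[sp$frame >= window[1] & sp$frame <= window[2], ]
  }
  ids <- sort(unique(sp$track_id))
  out <- data.frame(track_i = integer(), track_j = integer(),
                    n_frames = integer())
  if (length(ids) < 2) return(out)
  for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
    i <- ids[a]; j <- ids[b]
    ti <- sp[sp$track_id == i, ]
    tj <- sp[sp$track_id == j, ]
    common <- intersect(ti$frame, tj$frame)
    cnt <- 0L
    for (f in common) {
      pi <- ti[ti$frame == f, ]
      pj <- tj[tj$frame == f, ]
      d <- sqrt((pi$x - pj$x)^2 + (pi$y - pj$y)^2)
      if (d <= threshold) cnt <- cnt + 1L
    }
    if (cnt > 0L) {
      out <- rbind(out, data.frame(track_i = i, track_j = j, n_frames = cnt))
    }
  }
  rownames(out) <- NULL
  out
}

# --- graph oracles ---------------------------------------------------------

randomAdjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj + t(adj)
}

adjToNetwork <- function(adj) {
  n <- nrow(adj)
  hit <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
  edges <- if (nrow(hit)) data.frame(from = hit[, 1], to = hit[, 2]) else NULL
  EncounterNetwork(1:n, edges)
}

# all-pairs shortest paths by Floyd-Warshall
bfDistances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj == 1L, 1, Inf)
  diag(D) <- 0
  for (k in 1:n) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

bfMeanDegree <- function(adj) mean(rowSums(adj))

bfEfficiency <- function(adj) {
  n <- nrow(adj)
  D <- bfDistances(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bfComponentMembership <- function(adj) {
  D <- bfDistances(adj)
  n <- nrow(adj)
  memb <- rep(NA_integer_, n)
  comp <- 0L
  for (i in 1:n) {
    if (is.na(memb[i])) {
      comp <- comp + 1L
      memb[is.finite(D[i, ])] <- comp
    }
  }
  memb
}

bfNComponents <- function(adj) max(bfComponentMembership(adj))

bfDiameterLargestComp <- function(adj) {
  memb <- bfComponentMembership(adj)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    # component containing the smallest node index
    firsts <- vapply(big, function(k) min(which(memb == k)), numeric(1))
    big <- big[which.min(firsts)]
  }
  keep <- which(memb == big)
  if (length(keep) < 2) return(NA_real_)
  D <- bfDistances(adj[keep, keep, drop = FALSE])
  max(D[is.finite(D)])
}

# betweenness by BFS shortest-path counting and direct pair crediting
bfBetweenness <- function(adj) {
  n <- nrow(adj)
  D <- bfDistances(adj)
  sigma <- matrix(0, n, n)  # sigma[s, v] = number of shortest s-v paths
  for (s in 1:n) {
    sigma[s, s] <- 1
    dmax <- max(D[s, is.finite(D[s, ])])
    if (dmax >= 1) for (dd in 1:dmax) {
      for (v in which(D[s, ] == dd)) {
        preds <- which(adj[, v] == 1L & D[s, ] == dd - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  btw <- numeric(n)
  if (n < 3) return(btw)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    onPath <- is.finite(D[s, ]) & is.finite(D[t, ]) &
      (D[s, ] + D[t, ] == D[s, t])
    onPath[c(s, t)] <- FALSE
    if (any(onPath)) {
      btw[onPath] <- btw[onPath] +
        sigma[s, onPath] * sigma[t, onPath] / sigma[s, t]
    }
  }
  btw
}

# rigid motion applied to a trajectory set: rotate by theta then translate
rigidMotion <- function(ts, theta, dx, dy) {
  sp <- spots(ts)
  x2 <- sp$x * cos(theta) - sp$y * sin(theta) + dx
  y2 <- sp$x * sin(theta) + sp$y * cos(theta) + dy
  makeTs(sp$track_id, sp$frame, x2, y2, dt = frameIntervalS(ts),
         nFrames = nFrames(ts), kind = organelleKind(ts))
}

# uniform-random cell: fresh uniform positions each frame (spatial
# randomness null for the enrichment statistic)
csrCell <- function(nMito, nChloro, domain, nFrames, dt = 2) {
  sp <- expand.grid(frame = 0:(nFrames - 1), track_id = 0:(nMito - 1))
  sp$x <- stats::runif(nrow(sp), 0, domain)
  sp$y <- stats::runif(nrow(sp), 0, domain)
  m <- makeTs(sp$track_id, sp$frame, sp$x, sp$y, dt = dt)
  cx <- stats::runif(nChloro, 0, domain)
  cy <- stats::runif(nChloro, 0, domain)
  ch <- makeTs(rep(0:(nChloro - 1), each = nFrames),
               rep(0:(nFrames - 1), times = nChloro),
               rep(cx, each = nFrames), rep(cy, each = nFrames),
               dt = dt, nFrames = nFrames, kind = "chloroplast")
  list(mito = m, chloro = ch, area = domain^2)
}
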