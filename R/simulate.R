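# Agent-based 2D motion simulator.
#
# Emulates the phenomenology the analysis assumes: a per-cell population of
# mitochondria showing a mixture of static, diffusive and ballistic motion
# in a bounded quasi-2D domain, with optional sticking (clustering) to mimic
# aggregation phenotypes, and optional static chloroplast discs.

# Largest-remainder apportionment of n items to fractions; counts sum to n
# and an exact fraction (e.g. 0.3 of 100) is recovered exactly.
.apportion <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# Mirror-fold a coordinate vector into [0, hi] (reflecting boundary).
.foldReflect <- function(p, hi) {
  q <- p %% (2 * hi)
  ifelse(q > hi, 2 * hi - q, q)
}

#' Simulate one cell
#'
#' Runs the agent-based motion model described by a
#' [SimulationConfig-class]. Tracks are assigned motion classes by exact
#' largest-remainder apportionment of the configured fractions. Diffusive
#' movers take Gaussian steps with per-axis variance `2 * D * dt`;
#' ballistic movers advance `v * dt` along a heading kept with probability
#' `directionPersistence` per frame; static movers do not move. Boundaries
#' reflect: diffusive positions are mirror-folded into the domain, while
#' ballistic movers reflect their heading and retake the full step, so
#' their per-frame displacement is exactly `v * dt`.
#'
#' When clustering is enabled (`stickingProb > 0`), pairs within
#' `attractionRadiusUm` of each other merge clusters with `stickingProb`
#' per frame; a cluster moves as one body (the single Brownian/ballistic
#' update drawn for one randomly chosen member is applied to all members,
#' so clusters keep the mobility mix of their membership), members mill
#' within the cluster with an independent Brownian jitter of coefficient
#' `memberJitterCoeff`, and each non-singleton member leaves its cluster
#' with `unstickingProb` per frame.
#'
#' Chloroplasts are static discs of radius `chloroRadiusUm` placed
#' uniformly at random without overlap (bounded retries; a configuration
#' error is raised if placement is infeasible).
#'
#' Identical configurations (including seed) give identical output; the
#' generator algorithm is pinned (Mersenne-Twister, inversion,
#' rejection sampling) independent of the session's RNG settings.
#'
#' @param cfg a [SimulationConfig-class].
#' @param cellId,genotype labels for the resulting [CellRecord-class].
#' @return A [SimulatedCell-class]; use [cellRecord()] for the analysis
#'   view and [motionClasses()] / [clusterHistory()] for ground truth.
#' @examples
#' sc <- simulateCell(simulationConfig(nMito = 20, nFrames = 30, seed = 42))
#' cellRecord(sc)
#' @export
simulateCell <- function(cfg, cellId = "cell1", genotype = "synthetic") {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  suppressWarnings(set.seed(cfg@seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  n <- cfg@nMito
  nf <- cfg@nFrames
  dt <- cfg@frameIntervalS
  w <- cfg@domainUm[1L]
  h <- cfg@domainUm[2L]
  stopifnot(n >= 1L)

  counts <- .apportion(cfg@fractions, n)
  classes <- sample(rep(c("static", "diffusive", "ballistic"), counts))
  pos <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
  heading <- stats::runif(n, 0, 2 * pi)
  sigma <- sqrt(2 * cfg@diffusionCoeff * dt)
  stepLen <- cfg@ballisticSpeed * dt
  if (stepLen >= min(w, h)) {
    stop("ballistic step exceeds domain size; reduce speed or frame interval")
  }

  chloroCentres <- NULL
  if (cfg@nChloro > 0L) {
    chloroCentres <- .placeChloroplasts(cfg@nChloro, w, h, cfg@chloroRadiusUm)
  }

  clusteringOn <- cfg@clustering$stickingProb > 0
  attract <- cfg@clustering$attractionRadiusUm
  pStick <- cfg@clustering$stickingProb
  pUnstick <- cfg@clustering$unstickingProb
  clus <- seq_len(n)

  X <- array(NA_real_, dim = c(nf, n, 2L))
  X[1L, , ] <- pos
  clusterHist <- NULL
  if (clusteringOn) {
    clusterHist <- matrix(NA_integer_, nf, n)
    clusterHist[1L, ] <- clus
  }

  isDiff <- classes == "diffusive"
  isBall <- classes == "ballistic"

  if (nf > 1L) for (f in 2L:nf) {
    if (clusteringOn) {
      # release: each member of a multi-member cluster may leave
      sizes <- table(clus)
      inCluster <- which(clus %in% as.integer(names(sizes)[sizes > 1L]))
      if (length(inCluster)) {
        leave <- inCluster[stats::runif(length(inCluster)) < pUnstick]
        if (length(leave)) clus[leave] <- n + (f - 1L) * n + leave
      }
      # stick: pairs currently within the attraction radius merge clusters
      d <- as.matrix(stats::dist(pos))
      cand <- which(d <= attract & upper.tri(d), arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1L]; j <- cand[k, 2L]
          if (clus[i] != clus[j] && stats::runif(1) < pStick) {
            clus[clus == clus[j]] <- clus[i]
          }
        }
      }
    }

    disp <- matrix(0, n, 2L)
    nd <- sum(isDiff)
    if (nd) disp[isDiff, ] <- matrix(stats::rnorm(2L * nd, 0, sigma), nd, 2L)
    nb <- sum(isBall)
    if (nb) {
      bl <- which(isBall)
      turn <- stats::runif(nb) >= cfg@directionPersistence
      if (any(turn)) heading[bl[turn]] <- stats::runif(sum(turn), 0, 2 * pi)
      disp[bl, ] <- stepLen * cbind(cos(heading[bl]), sin(heading[bl]))
    }

    if (clusteringOn) {
      # a cluster moves as one body: the update drawn for one randomly
      # chosen member this frame is applied to all members, so clusters
      # keep wandering with the mobility mix of their membership; members
      # additionally mill inside the cluster with a small Brownian jitter
      jitterSd <- sqrt(2 * cfg@clustering$memberJitterCoeff * dt)
      for (cid in sort(unique(clus))) {
        members <- which(clus == cid)
        if (length(members) > 1L) {
          lead <- members[sample.int(length(members), 1L)]
          nm <- length(members)
          jit <- if (jitterSd > 0) {
            matrix(stats::rnorm(2L * nm, 0, jitterSd), nm, 2L)
          } else {
            matrix(0, nm, 2L)
          }
          disp[members, 1L] <- disp[lead, 1L] + jit[, 1L]
          disp[members, 2L] <- disp[lead, 2L] + jit[, 2L]
        }
      }
    }

    newpos <- pos + disp
    # ballistic singletons: reflect heading components so the full step is
    # retaken inside the domain (|step| stays exactly v*dt)
    if (nb) {
      bl <- which(isBall)
      free <- if (clusteringOn) {
        sizes <- table(clus)
        bl[as.integer(sizes[as.character(clus[bl])]) == 1L]
      } else {
        bl
      }
      for (i in free) {
        for (pass in 1:2) {
          ux <- cos(heading[i]); uy <- sin(heading[i])
          px <- pos[i, 1L] + stepLen * ux
          py <- pos[i, 2L] + stepLen * uy
          okx <- px >= 0 && px <= w
          oky <- py >= 0 && py <= h
          if (okx && oky) break
          if (!okx) ux <- -ux
          if (!oky) uy <- -uy
          heading[i] <- atan2(uy, ux)
        }
        newpos[i, 1L] <- pos[i, 1L] + stepLen * cos(heading[i])
        newpos[i, 2L] <- pos[i, 2L] + stepLen * sin(heading[i])
      }
    }
    # everything else: mirror-fold into the domain
    newpos[, 1L] <- .foldReflect(newpos[, 1L], w)
    newpos[, 2L] <- .foldReflect(newpos[, 2L], h)
    pos <- newpos
    X[f, , ] <- pos
    if (clusteringOn) clusterHist[f, ] <- clus
  }

  trackIds <- 0:(n - 1L)
  sp <- data.frame(
    track_id = rep(trackIds, each = nf),
    frame = rep(0:(nf - 1L), times = n),
    x = as.vector(X[, , 1L]),
    y = as.vector(X[, , 2L])
  )
  mitoTs <- TrajectorySet(sp, frameIntervalS = dt, nFrames = nf)
  chloroTs <- NULL
  if (!is.null(chloroCentres)) {
    nc <- nrow(chloroCentres)
    chloroTs <- TrajectorySet(
      data.frame(track_id = rep(0:(nc - 1L), each = nf),
                 frame = rep(0:(nf - 1L), times = nc),
                 x = rep(chloroCentres[, 1L], each = nf),
                 y = rep(chloroCentres[, 2L], each = nf)),
      frameIntervalS = dt, nFrames = nf, organelleKind = "chloroplast")
  }
  cell <- CellRecord(cellId = cellId, genotype = genotype, mito = mitoTs,
                     chloro = chloroTs, cellAreaUm2 = w * h, pixelScale = 5)
  names(classes) <- as.character(trackIds)
  if (!is.null(clusterHist)) colnames(clusterHist) <- as.character(trackIds)
  new("SimulatedCell", cell = cell, motionClass = classes,
      clusterHistory = clusterHist, chloroCentres = chloroCentres)
}

# Uniform non-overlapping disc placement with bounded retries.
.placeChloroplasts <- function(nChloro, w, h, r, maxTries = 10000L) {
  if (2 * r >= w || 2 * r >= h) {
    stop("configuration error: chloroplast radius too large for domain")
  }
  centres <- matrix(NA_real_, nChloro, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < nChloro && tries < maxTries) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, r, w - r), stats::runif(1, r, h - r))
    ok <- TRUE
    if (placed > 0L) {
      dd <- sqrt((centres[seq_len(placed), 1L] - cand[1L])^2 +
                 (centres[seq_len(placed), 2L] - cand[2L])^2)
      ok <- all(dd >= 2 * r)
    }
    if (ok) {
      placed <- placed + 1L
      centres[placed, ] <- cand
    }
  }
  if (placed < nChloro) {
    stop("configuration error: could not place ", nChloro,
         " non-overlapping chloroplasts in the domain")
  }
  centres
}

#' Update a simulation configuration
#'
#' Returns a copy of `cfg` with the named constructor arguments replaced;
#' used by [makeCohort()] to express genotypes as config overrides.
#'
#' @param cfg a [SimulationConfig-class].
#' @param overrides named list of [simulationConfig()] arguments. The
#'   `clustering` override may be partial (only the fields to change).
#' @return A [SimulationConfig-class].
#' @export
updateConfig <- function(cfg, overrides) {
  args <- list(
    nMito = cfg@nMito, nChloro = cfg@nChloro, domainUm = cfg@domainUm,
    nFrames = cfg@nFrames, frameIntervalS = cfg@frameIntervalS,
    fractions = cfg@fractions, diffusionCoeff = cfg@diffusionCoeff,
    ballisticSpeed = cfg@ballisticSpeed,
    directionPersistence = cfg@directionPersistence,
    clustering = cfg@clustering, chloroRadiusUm = cfg@chloroRadiusUm,
    seed = cfg@seed
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(args))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      if (nm == "clustering") {
        args$clustering[names(overrides$clustering)] <- overrides$clustering
      } else {
        args[[nm]] <- overrides[[nm]]
      }
    }
  }
  do.call(simulationConfig, args)
}

#' Simulate a cohort of cells across genotypes
#'
#' Stands in for an imaging cohort: for each genotype, `nCellsPerGenotype`
#' cells are simulated from the base configuration with that genotype's
#' overrides applied and a per-cell seed derived deterministically from
#' `seed`, so the same call always returns the same cohort.
#'
#' @param baseCfg a [SimulationConfig-class] shared by all genotypes.
#' @param genotypeSpecs named list; each element is a (possibly empty) list
#'   of config overrides for that genotype (see [updateConfig()]).
#' @param nCellsPerGenotype cells per genotype.
#' @param seed integer master seed for the cohort.
#' @return List of [CellRecord-class] objects with genotype labels and
#'   unique cell ids.
#' @examples
#' cohort <- makeCohort(
#'   simulationConfig(nMito = 30, nFrames = 40),
#'   list(wt = list(), sticky = list(clustering = list(stickingProb = 0.8))),
#'   nCellsPerGenotype = 2, seed = 7
#' )
#' vapply(cohort, cellId, character(1))
#' @export
makeCohort <- function(baseCfg, genotypeSpecs, nCellsPerGenotype, seed) {
  stopifnot(is.list(genotypeSpecs), length(names(genotypeSpecs)) > 0)
  cells <- list()
  gi <- 0L
  for (g in names(genotypeSpecs)) {
    gi <- gi + 1L
    cfg <- updateConfig(baseCfg, genotypeSpecs[[g]])
    for (i in seq_len(nCellsPerGenotype)) {
      cellSeed <- as.integer(
        ((seed %% 1e6) * 1009 + gi * 100003 + i) %% 2147483647)
      cfgI <- updateConfig(cfg, list(seed = cellSeed))
      sc <- simulateCell(cfgI, cellId = sprintf("%s_cell%02d", g, i),
                         genotype = g)
      cells[[length(cells) + 1L]] <- cellRecord(sc)
    }
  }
  cells
}
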