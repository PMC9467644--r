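# The agent-based motion simulator: limiting behaviours, calibration,
# confinement, determinism.

test_that("all-static cells never move", {
  cfg <- simulationConfig(nMito = 25, nFrames = 40, seed = 2,
                          fractions = c(static = 1, diffusive = 0,
                                        ballistic = 0))
  sp <- spots(mito(cellRecord(simulateCell(cfg))))
  for (id in unique(sp$track_id)) {
    tr <- sp[sp$track_id == id, ]
    expect_equal(length(unique(tr$x)), 1L)
    expect_equal(length(unique(tr$y)), 1L)
  }
})

test_that("pure ballistic motion with full persistence steps exactly v*dt", {
  v <- 0.4
  cfg <- simulationConfig(nMito = 40, nFrames = 60, seed = 3,
                          ballisticSpeed = v, directionPersistence = 1,
                          fractions = c(static = 0, diffusive = 0,
                                        ballistic = 1))
  ts <- mito(cellRecord(simulateCell(cfg)))
  sp <- spots(ts)
  expected <- v * frameIntervalS(ts)
  for (id in unique(sp$track_id)) {
    tr <- sp[sp$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_equal(step, rep(expected, length(step)), tolerance = 1e-12)
  }
})

test_that("diffusive mean squared step matches 4*D*dt", {
  D <- 0.05; dt <- 2
  cfg <- simulationConfig(nMito = 200, nFrames = 120, seed = 7,
                          frameIntervalS = dt, diffusionCoeff = D,
                          fractions = c(static = 0, diffusive = 1,
                                        ballistic = 0))
  sp <- spots(mito(cellRecord(simulateCell(cfg))))
  sq <- unlist(lapply(split(sp, sp$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    diff(tr$x)^2 + diff(tr$y)^2
  }))
  expect_gt(length(sq), 20000)
  expect_equal(mean(sq), 4 * D * dt, tolerance = 0.05)
})

test_that("positions stay confined to the domain", {
  cfg <- simulationConfig(nMito = 60, nFrames = 80, domainUm = c(20, 30),
                          seed = 9, ballisticSpeed = 2,
                          clustering = list(stickingProb = 0.5))
  sp <- spots(mito(cellRecord(simulateCell(cfg))))
  expect_true(all(sp$x >= 0 & sp$x <= 20))
  expect_true(all(sp$y >= 0 & sp$y <= 30))
})

test_that("static fraction is recovered exactly from path lengths", {
  cfg <- simulationConfig(nMito = 100, nFrames = 50, seed = 4)
  sp <- spots(mito(cellRecord(simulateCell(cfg))))
  pathLen <- vapply(split(sp, sp$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  }, numeric(1))
  expect_equal(mean(pathLen == 0), 0.3)
})

test_that("ground truth matches programmed classes and track ids", {
  sc <- simulateCell(simulationConfig(nMito = 50, nFrames = 30, seed = 6))
  classes <- motionClasses(sc)
  expect_setequal(as.integer(names(classes)),
                  trackIds(mito(cellRecord(sc))))
  expect_equal(sum(classes == "static"), 15L)
  expect_equal(sum(classes == "diffusive"), 25L)
  expect_equal(sum(classes == "ballistic"), 10L)
})

test_that("identical seeds give identical cells; cohorts are reproducible", {
  cfg <- simulationConfig(nMito = 30, nFrames = 25, nChloro = 4, seed = 11)
  a <- simulateCell(cfg)
  b <- simulateCell(cfg)
  expect_identical(spots(mito(cellRecord(a))), spots(mito(cellRecord(b))))
  expect_identical(spots(chloro(cellRecord(a))),
                   spots(chloro(cellRecord(b))))

  specs <- list(wt = list(), mut = list(diffusionCoeff = 0.1))
  base <- simulationConfig(nMito = 20, nFrames = 20)
  c1 <- makeCohort(base, specs, nCellsPerGenotype = 3, seed = 5)
  c2 <- makeCohort(base, specs, nCellsPerGenotype = 3, seed = 5)
  expect_equal(length(c1), 6L)
  ids <- vapply(c1, cellId, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  for (k in seq_along(c1)) {
    expect_identical(spots(mito(c1[[k]])), spots(mito(c2[[k]])))
    expect_identical(genotype(c1[[k]]), genotype(c2[[k]]))
  }
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulateCell(simulationConfig(nMito = 5, nFrames = 5, seed = 1)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("chloroplasts are non-overlapping discs; infeasible configs error", {
  sc <- simulateCell(simulationConfig(nMito = 5, nFrames = 5, nChloro = 10,
                                      seed = 8))
  ch <- spots(chloro(cellRecord(sc)))
  first <- ch[ch$frame == 0, ]
  d <- as.matrix(dist(first[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 3))  # centres >= 2 * 1.5 um apart
  # static discs: positions constant over frames
  expect_equal(nrow(unique(ch[, c("track_id", "x", "y")])), 10L)

  expect_error(
    simulateCell(simulationConfig(nMito = 2, nFrames = 2, nChloro = 50,
                                  domainUm = c(10, 10), seed = 1)),
    "configuration error")
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(simulationConfig(fractions = c(-0.1, 0.6, 0.5)),
               "non-negative")
  expect_error(simulationConfig(domainUm = c(-5, 10)), "positive")
  expect_error(updateConfig(simulationConfig(), list(bogus = 1)),
               "unknown config field")
})

test_that("a strongly sticking cohort packs closer than a spread one", {
  specs <- list(
    spread = list(),
    clustered = list(clustering = list(stickingProb = 0.8,
                                       unstickingProb = 0.02))
  )
  cells <- makeCohort(simulationConfig(), specs, nCellsPerGenotype = 10,
                      seed = 11)
  summ <- summarizeCohort(cells)
  rows <- summ[summ$statistic == "intermito_distance", ]
  gm <- tapply(rows$value, rows$genotype, mean)
  expect_lt(gm[["clustered"]], gm[["spread"]])
})

test_that("sticky clusters co-move while stuck", {
  # rigid co-movement (jitter off) so cluster-mates displace identically
  cfg <- simulationConfig(nMito = 40, nFrames = 60, seed = 13,
                          clustering = list(stickingProb = 0.9,
                                            unstickingProb = 0.01,
                                            memberJitterCoeff = 0))
  sc <- simulateCell(cfg)
  hist <- clusterHistory(sc)
  expect_false(is.null(hist))
  sp <- spots(mito(cellRecord(sc)))
  pos <- function(id, f) {
    r <- sp[sp$track_id == id & sp$frame == f, ]
    c(r$x, r$y)
  }
  # a pair sharing a cluster label in row f moved jointly during the step
  # into 0-based frame f-1; their displacements over that step must match
  found <- FALSE
  for (f in 2:nrow(hist)) {
    cl <- hist[f, ]
    shared <- names(cl)[duplicated(cl) | duplicated(cl, fromLast = TRUE)]
    for (cid in unique(cl[shared])) {
      ids <- as.integer(names(cl)[cl == cid])
      if (length(ids) < 2) next
      d1 <- pos(ids[1], f - 1) - pos(ids[1], f - 2)
      d2 <- pos(ids[2], f - 1) - pos(ids[2], f - 2)
      expect_equal(d1, d2, tolerance = 1e-9)
      found <- TRUE
      break
    }
    if (found) break
  }
  expect_true(found)
})
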