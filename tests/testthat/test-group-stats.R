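# Nonparametric group comparison protocol.

test_that("identical two groups give p = 1", {
  res <- compareTwo(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "wilcoxon_rank_sum")
})

test_that("fully separated small groups give the enumeration p-value", {
  res <- compareTwo(c(1, 2, 3, 4), c(10, 11, 12, 13))
  # U = 0; of the choose(8, 4) = 70 equally likely rank assignments only
  # the two complete separations are as extreme: p = 2/70
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(unname(res$statistic), 0)
})

test_that("exact vs asymptotic switch follows sample size and ties", {
  big <- compareTwo(rnorm(20), rnorm(20))
  expect_match(big$method, "approximation")
  tied <- compareTwo(c(1, 1, 2), c(2, 3, 4))
  expect_match(tied$method, "approximation")
  small <- compareTwo(c(1, 2), c(3, 4))
  expect_equal(small$method, "exact")
})

test_that("rank-sum p is invariant under monotone transformation", {
  set.seed(51)
  x <- rnorm(12); y <- rnorm(12, 1)
  expect_equal(compareTwo(exp(x), exp(y))$p_value,
               compareTwo(x, y)$p_value)
})

test_that("empty groups are rejected", {
  expect_error(compareTwo(numeric(), 1:3), "non-empty")
  expect_error(compareMulti(list(a = 1:3, b = numeric(), c = 1:3)),
               "non-empty")
})

test_that("three identical groups give H = 0, p = 1", {
  res <- compareMulti(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
})

test_that("Kruskal-Wallis H matches hand rank arithmetic", {
  res <- compareMulti(list(a = 1:3, b = 4:6, c = 7:9))
  # ranks are 1..9 exactly; H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  # = 12/90 * 3*((2-5)^2 + (5-5)^2 + (8-5)^2) = 7.2
  expect_equal(unname(res$statistic), 7.2, tolerance = 1e-12)
  expect_equal(res$test, "kruskal_wallis")
})

test_that("two groups are directed to compareTwo", {
  expect_error(compareMulti(list(a = 1:3, b = 4:6)), "compareTwo")
})

test_that("Dunn post hoc is BH-adjusted, ordered and symmetric", {
  set.seed(61)
  groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res <- compareMulti(groups)
  ph <- res$posthoc
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_adj <= 1))
  # BH preserves the ordering of raw p-values
  expect_equal(order(ph$p_adj), order(ph$p_raw))

  # reordering the groups flips z signs but preserves p-values
  rev <- compareMulti(rev(groups))$posthoc
  key <- function(d) paste(pmin(d$group1, d$group2),
                           pmax(d$group1, d$group2))
  m <- match(key(ph), key(rev))
  expect_equal(abs(ph$z), abs(rev$z[m]), tolerance = 1e-12)
  expect_equal(ph$p_raw, rev$p_raw[m], tolerance = 1e-12)
})

test_that("Dunn z matches a direct formula evaluation with ties", {
  values <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 11, 11)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  res <- compareMulti(split(values, g))
  # independent evaluation of the Dunn statistic for pair (a, b)
  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  s2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  zab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / sqrt(s2 * (1/4 + 1/4))
  ph <- res$posthoc
  expect_equal(ph$z[ph$group1 == "a" & ph$group2 == "b"], zab,
               tolerance = 1e-12)
})

test_that("the rank-sum test detects a 2-SD location shift reliably", {
  # per-cell summary values with a programmed 2-SD shift, n = 20 per group
  set.seed(21)
  hits <- 0L
  for (rep in 1:200) {
    x <- rnorm(20, 0, 1)
    y <- rnorm(20, 2, 1)
    if (compareTwo(x, y)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("summarizeCohort returns one tidy row per cell, checkpoint and statistic", {
  base <- simulationConfig(nMito = 15, nFrames = 20)
  cells <- makeCohort(base, list(wt = list(), mut = list()),
                      nCellsPerGenotype = 3, seed = 17)
  summ <- summarizeCohort(cells, checkpoints = c(9L, 19L))
  expect_s3_class(summ, "data.frame")
  perStat <- table(summ$statistic, summ$checkpoint_frame)
  expect_true(all(perStat == 6L))  # 6 cells per statistic per checkpoint
  expect_setequal(unique(summ$genotype), c("wt", "mut"))
  # deterministic re-run
  summ2 <- summarizeCohort(makeCohort(base, list(wt = list(), mut = list()),
                                      nCellsPerGenotype = 3, seed = 17),
                           checkpoints = c(9L, 19L))
  expect_identical(summ, summ2)
})

test_that("summarizeCohort includes enrichment when chloroplasts exist", {
  cfg <- simulationConfig(nMito = 20, nFrames = 15, nChloro = 3, seed = 19)
  cells <- makeCohort(cfg, list(wt = list()), nCellsPerGenotype = 2,
                      seed = 23)
  summ <- summarizeCohort(cells)
  expect_true("enrichment" %in% summ$statistic)
})

test_that("compareCohort dispatches on the number of groups", {
  base <- simulationConfig(nMito = 15, nFrames = 15)
  cells <- makeCohort(base, list(a = list(), b = list(), c = list()),
                      nCellsPerGenotype = 3, seed = 29)
  summ <- summarizeCohort(cells)
  multi <- compareCohort(summ, "mean_degree")
  expect_equal(multi$test, "kruskal_wallis")
  expect_false(is.null(multi$posthoc))
  two <- compareCohort(summ[summ$genotype != "c", ], "mean_degree")
  expect_equal(two$test, "wilcoxon_rank_sum")
})

test_that("cohort boxplots build without error", {
  base <- simulationConfig(nMito = 12, nFrames = 10)
  cells <- makeCohort(base, list(wt = list(), mut = list()),
                      nCellsPerGenotype = 2, seed = 31)
  summ <- summarizeCohort(cells)
  p <- plotCohort(summ, "mean_degree")
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 2L)
})
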