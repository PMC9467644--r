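# Nonparametric comparison of per-cell summary statistics across genotype
# groups: Wilcoxon rank sum for two groups, Kruskal-Wallis with post-hoc
# Dunn tests (Benjamini-Hochberg adjusted across the pairwise set) for
# three or more. Correction is applied only within a Dunn pairwise set,
# never across different summary statistics.

#' Compare two groups (Wilcoxon rank sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test on per-cell values. The
#' exact distribution is used when the combined sample size is at most 25
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The path taken is recorded in `$method`.
#'
#' @param x,y numeric vectors of per-cell values for the two groups.
#' @param groupNames labels for the two groups.
#' @param statisticName optional name of the summary statistic compared.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`, default)
#'   the exact test.
#' @return A list of class `"groupComparison"`: `statistic_name`, `test`
#'   (`"wilcoxon_rank_sum"`), `groups` (data.frame label, n), `statistic`
#'   (U), `p_value`, `method`, `posthoc` (`NULL`).
#' @examples
#' compareTwo(c(1, 2, 3, 4), c(10, 11, 12, 13))$p_value  # 2/70
#' @export
compareTwo <- function(x, y, groupNames = c("group1", "group2"),
                       statisticName = NA_character_, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 25L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  structure(list(
    statistic_name = statisticName,
    test = "wilcoxon_rank_sum",
    groups = data.frame(label = groupNames, n = c(length(x), length(y))),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else
      "normal approximation with continuity and tie correction",
    posthoc = NULL
  ), class = "groupComparison")
}

#' Compare three or more groups (Kruskal-Wallis + Dunn post hoc)
#'
#' Kruskal-Wallis rank-sum test with tie correction and chi-square
#' p-value, followed by pairwise Dunn z-tests on the shared pooled ranks.
#' Dunn raw p-values are two-sided normal tail probabilities; adjusted
#' p-values are Benjamini-Hochberg across the pairwise set only.
#'
#' @param groups named list (length >= 3) of numeric vectors of per-cell
#'   values.
#' @param statisticName optional name of the summary statistic compared.
#' @return A list of class `"groupComparison"`: `statistic_name`, `test`
#'   (`"kruskal_wallis"`), `groups`, `statistic` (H), `p_value`, `method`,
#'   and `posthoc`, a data.frame of pairwise `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`.
#' @examples
#' compareMulti(list(a = 1:3, b = 4:6, c = 7:9))$statistic  # H = 7.2
#' @export
compareMulti <- function(groups, statisticName = NA_character_) {
  if (!is.list(groups) || is.null(names(groups))) {
    stop("groups must be a named list of numeric vectors")
  }
  if (length(groups) < 3L) {
    stop("fewer than 3 groups: use compareTwo() for a two-group comparison")
  }
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- stats::kruskal.test(values, g)
  posthoc <- .dunnTest(values, g)
  structure(list(
    statistic_name = statisticName,
    test = "kruskal_wallis",
    groups = data.frame(label = names(groups), n = as.integer(lengths(groups))),
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    method = "chi-square approximation with tie correction",
    posthoc = posthoc
  ), class = "groupComparison")
}

# Dunn (1964) pairwise z-tests on pooled ranks with tie correction;
# two-sided p-values, BH-adjusted across the pairwise set.
.dunnTest <- function(values, g) {
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tiecounts <- table(values)
  C <- sum(tiecounts^3 - tiecounts) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - C
  labs <- levels(g)
  pairs <- utils::combn(labs, 2L)
  z <- apply(pairs, 2L, function(p) {
    (rbar[p[1L]] - rbar[p[2L]]) /
      sqrt(s2 * (1 / n[p[1L]] + 1 / n[p[2L]]))
  })
  pRaw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             z = as.numeric(z), p_raw = pRaw,
             p_adj = stats::p.adjust(pRaw, method = "BH"))
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("%s comparison%s\n", x$test,
              if (is.na(x$statistic_name)) "" else
                paste0(" of ", x$statistic_name)))
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", x$groups$label, x$groups$n),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc Dunn (BH-adjusted):\n")
    ph <- x$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("    %s vs %s: z = %.3f, p_adj = %.4g\n",
                  ph$group1[i], ph$group2[i], ph$z[i], ph$p_adj[i]))
    }
  }
  invisible(x)
}

#' Summarise a cohort of cells
#'
#' Runs the full per-cell pipeline — physical statistics, encounter
#' network, network statistics, and (when chloroplasts are present)
#' enrichment — for every cell at every checkpoint, and returns a tidy
#' long-format table with one row per (cell, checkpoint, statistic), the
#' unit plotted as one point in a cohort figure. Per-cell failures are
#' logged as warnings and skipped rather than aborting the cohort.
#'
#' @param cells list of [CellRecord-class] objects.
#' @param thresholdUm encounter / co-localization threshold, µm
#'   (default 1.6).
#' @param checkpoints frame indices ending each accumulation window
#'   `[0, cp]`; default is the full video only.
#' @param dUm chloroplast adjacency distance for enrichment, µm
#'   (default 3).
#' @param includeIsolated passed to [meanDegree()].
#' @return data.frame with columns `cell_id`, `genotype`,
#'   `checkpoint_frame`, `window_s`, `statistic`, `value`.
#' @export
summarizeCohort <- function(cells, thresholdUm = 1.6, checkpoints = NULL,
                            dUm = 3, includeIsolated = TRUE) {
  stopifnot(length(cells) > 0)
  rows <- list()
  for (cell in cells) {
    ts <- mito(cell)
    cps <- checkpoints %||% (nFrames(ts) - 1L)
    res <- tryCatch({
      lapply(cps, function(cp) {
        tsw <- windowTrajectories(ts, 0L, cp)
        phys <- suppressWarnings(physicalSummary(tsw, thresholdUm))
        net <- networkSummary(buildNetwork(ts, thresholdUm, c(0L, cp)),
                              includeIsolated = includeIsolated)
        vals <- c(
          mean_speed = phys$mean_speed_um_per_frame,
          median_speed = phys$median_speed_um_per_frame,
          intermito_distance = phys$mean_intermito_distance_um,
          coloc_time = phys$mean_coloc_time_frames,
          mean_degree = net$mean_degree,
          efficiency = net$efficiency,
          diameter = net$diameter,
          mean_betweenness = net$mean_betweenness,
          n_components = net$n_components,
          n_nodes = net$n_nodes,
          n_edges = net$n_edges
        )
        if (!is.null(chloro(cell))) {
          chw <- windowTrajectories(chloro(cell), 0L, cp)
          enr <- suppressWarnings(
            chloroplastEnrichment(tsw, chw, cellArea(cell), dUm))
          vals <- c(vals, enrichment = enr$meanE)
        }
        data.frame(cell_id = cellId(cell), genotype = genotype(cell),
                   checkpoint_frame = as.integer(cp),
                   window_s = (cp + 1) * frameIntervalS(ts),
                   statistic = names(vals), value = as.numeric(vals))
      })
    }, error = function(e) {
      warning("cell ", cellId(cell), " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows <- c(rows, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare one statistic across genotypes in a cohort table
#'
#' Selects one summary statistic (and checkpoint) from a
#' [summarizeCohort()] table, splits the per-cell values by group, and
#' dispatches to [compareTwo()] for two groups or [compareMulti()] for
#' three or more.
#'
#' @param summary a [summarizeCohort()] table.
#' @param statistic one of the `statistic` values in the table.
#' @param groupCol grouping column (default `"genotype"`; any column works,
#'   e.g. a day/night factor).
#' @param checkpoint checkpoint frame to compare at; default the latest.
#' @return A `"groupComparison"` object.
#' @export
compareCohort <- function(summary, statistic, groupCol = "genotype",
                          checkpoint = NULL) {
  stopifnot(statistic %in% summary$statistic)
  checkpoint <- checkpoint %||% max(summary$checkpoint_frame)
  rows <- summary[summary$statistic == statistic &
                  summary$checkpoint_frame == checkpoint, , drop = FALSE]
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  groups <- split(rows$value, rows[[groupCol]])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  if (length(groups) == 2L) {
    compareTwo(groups[[1L]], groups[[2L]], groupNames = names(groups),
               statisticName = statistic)
  } else {
    compareMulti(groups, statisticName = statistic)
  }
}

#' Cohort boxplot of one summary statistic
#'
#' Standard cohort layout: per-group boxes (median, 25th/75th percentile,
#' whiskers to the most extreme value within 1.5 x IQR) with one jittered
#' point per cell.
#'
#' @param summary a [summarizeCohort()] table.
#' @param statistic statistic to plot.
#' @param groupCol grouping column (default `"genotype"`).
#' @param checkpoint checkpoint frame; default the latest.
#' @return A `ggplot` object.
#' @export
plotCohort <- function(summary, statistic, groupCol = "genotype",
                       checkpoint = NULL) {
  stopifnot(statistic %in% summary$statistic)
  checkpoint <- checkpoint %||% max(summary$checkpoint_frame)
  rows <- summary[summary$statistic == statistic &
                  summary$checkpoint_frame == checkpoint, , drop = FALSE]
  rows$group <- rows[[groupCol]]
  ggplot2::ggplot(rows, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 1.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, size = 1.5) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_classic()
}
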