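# ChondrioNet

Analysis of the collective — "social" — behaviour of mitochondria in
single plant cells, from particle-tracking trajectories.

Plant mitochondria are largely discrete individuals, and a cell's
chondriome balances two needs: staying evenly **spread** through the
cytoplasm, and **encountering** each other to allow fusion and exchange
of contents (including mtDNA). ChondrioNet quantifies both sides of this
trade-off from TrackMate-style spot exports of time-lapse microscopy:

* **Physical statistics** per cell: trajectory speed (µm/frame),
  per-frame nearest-neighbour inter-mitochondrial distance, pairwise
  co-localization time within a threshold (default 1.6 µm), and a
  chloroplast co-localization enrichment ratio
  `E = (Nc/Ac) / ((N−Nc)/(A−Ac))`, which is ~1 under a random
  arrangement of organelles.
* **Encounter networks**: an undirected graph per cell whose nodes are
  mitochondrial trajectories and whose edges record at least one close
  approach (≤ 1.6 µm) within the observation window. Networks accumulate
  over time; the package computes mean degree, global efficiency
  `E(G) = 1/(n(n−1)) Σ_{i≠j} 1/d(i,j)`, diameter (largest component),
  betweenness centrality and connected-component count.
* **Group comparison**: per-cell summaries compared across genotypes by
  two-sided Wilcoxon rank-sum tests (two groups) or Kruskal–Wallis with
  post-hoc Dunn z-tests and Benjamini–Hochberg adjustment within the
  pairwise set (three or more), plus standard boxplot-with-points cohort
  figures.
* **A synthetic-cell simulator**: an agent-based 2D motion model
  (static / diffusive / ballistic mixtures, optional sticking/clustering
  with intra-cluster milling, static chloroplast discs, reflecting
  boundaries) with full ground truth, so the entire pipeline is testable
  and calibratable without microscopy data.

## Worked example

```r
library(ChondrioNet)

# simulate one cell: 80 mitochondria + 4 chloroplasts, 120 frames (233 s)
sc   <- simulateCell(simulationConfig(nMito = 80, nFrames = 120,
                                      nChloro = 4, seed = 42))
cell <- cellRecord(sc)
ts   <- mito(cell)

physicalSummary(ts)
#>   mean_speed_um_per_frame median_speed_um_per_frame mean_intermito_distance_um
#> 1               0.4335952                 0.5536397                   3.341395
#>   mean_coloc_time_frames mean_coloc_time_all_pairs n_tracks window_frames
#> 1               10.62879                 0.4439873       80           120

networkSummary(buildNetwork(ts))
#>   window_end_frame threshold_um n_nodes n_edges mean_degree efficiency diameter
#> 1              119          1.6      80     132         3.3  0.2052515       16
#>   mean_betweenness mean_betweenness_normalized n_components
#> 1           177.95                  0.05775722            6
```

Over 233 s these 80 mitochondria accumulated 132 pairwise encounters —
3.3 encounter partners each on average — into a network of 6 connected
components whose typical pair sits ~5 hops apart (efficiency 0.21).
Co-localizing pairs stayed within 1.6 µm for ~10.6 frames on average,
and the mean spacing to the nearest neighbour was 3.3 µm.

A two-genotype synthetic cohort, compared the way imaging cohorts are:

```r
cohort <- makeCohort(
  simulationConfig(),
  list(spread    = list(),
       clustered = list(clustering = list(stickingProb = 0.8,
                                          unstickingProb = 0.05,
                                          memberJitterCoeff = 0.05))),
  nCellsPerGenotype = 10, seed = 11)

summ <- summarizeCohort(cohort)
compareCohort(summ, "coloc_time")
#> wilcoxon_rank_sum comparison of coloc_time
#>   groups: clustered (n=10), spread (n=10)
#>   statistic = 98, p = 4.33e-05 (exact)

plotCohort(summ, "coloc_time")   # boxplot + one point per cell
```

The sticky genotype's mitochondria stay co-localized significantly
longer — the spacing-versus-encounters trade-off shifted towards
encounters.

Real data enter through `readTrackMateCsv()` (both the single-header
"simple" dialect and the multi-header TrackMate-7 dialect are
autodetected; pixel coordinates are calibrated with `pixelScale`, e.g. 5
px/µm) and `assembleCell()`; the frame interval in seconds is required
metadata. `writeCanonical()` / `readCanonical()` provide an exact
round-tripping tidy CSV format, and `exportNetwork()` writes edge lists
or GraphML.

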