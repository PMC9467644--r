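---
title: "Encounter networks of the chondriome: models, statistics and design choices"
author: "ChondrioNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter networks of the chondriome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChondrioNet)
```

## The scientific problem

Plant mitochondria are largely individual organelles. A cell's
chondriome — its whole mitochondrial population — faces a trade-off:
staying evenly spread supports local energy provision throughout the
cytoplasm, while coming together supports encounters, fusion and the
exchange of contents (including mtDNA, relevant when genome maintenance
is compromised). Time-lapse imaging of single hypocotyl cells, with
mitochondria tracked as point particles, lets both sides of the trade-off
be quantified:

* **physical statistics** describe spacing and motion: per-trajectory
  speed, per-frame nearest-neighbour distance, and the time pairs spend
  co-localized;
* **encounter ("social") network statistics** describe the accumulated
  web of close approaches: mean degree, global efficiency, diameter,
  betweenness centrality and component count.

ChondrioNet implements this pipeline from tracked trajectories onward,
plus an agent-based simulator so every stage can be exercised and
calibrated without microscopy data.

## Data model

A `TrajectorySet` holds the spots of one cell's tracked organelles
(track id, 0-based frame, x/y in µm). Positions are calibrated at read
time (`readTrackMateCsv(pixelScale =)` divides pixel coordinates; 5
px/µm is the typical calibration for this kind of confocal data).
`assembleCell()` combines mitochondrial and optional chloroplast sets
with metadata into a `CellRecord`. The acquisition frame interval cannot
be recovered from a spot table and is therefore *required* metadata
rather than an assumed constant.

Two deliberate choices in the reader:

* Each track id is one node identity for the whole video; tracker
  splits/merges are not resolved.
* Missing frames inside a track (gap closing, up to 2 frames by
  convention) are **not interpolated**. A track simply contributes
  nothing in frames where it has no spot. Interpolation would fabricate
  encounter evidence; the only place the gap is acknowledged is speed,
  where a step across a g-frame gap is divided by g (matching the
  tracker's gap-closing semantics, which treat the gap as continuous
  motion).

## Physical statistics

* **Speed** (µm/frame): per track, the mean of consecutive-spot
  displacements divided by their frame gaps; the cell-level value is the
  mean (and median) over tracks.
* **Inter-mitochondrial distance** (µm): per frame, each present
  mitochondrion's distance to its nearest present neighbour, averaged
  within the frame, then across frames. Averaging within frames first
  keeps crowded frames from dominating.
* **Co-localization time** (frames): per unordered pair, the number of
  frames both are present and within the threshold (default 1.6 µm, a
  characteristic close association just over one mitochondrion's
  length; the comparison is closed, `<=`). The headline cell statistic
  averages over pairs that ever co-localize — its natural scale is tens
  of frames — and the mean over *all* pairs is reported alongside, since
  the aggregation convention is genuinely ambiguous in the field.

All three are checked against brute-force enumeration oracles in the
test suite, and are invariant under rigid motions of the coordinate
system.

## Chloroplast co-localization enrichment

Per frame, with `N` mitochondria present, `Nc` of them within `d` of the
centre of their nearest chloroplast, cell area `A` and
chloroplast-adjacent area `Ac`:

```
E = (Nc / Ac) / ((N - Nc) / (A - Ac))
```

`d` defaults to 3 µm (twice the typical 1.5 µm chloroplast radius) and
`Ac` to `pi * d^2` summed over chloroplasts present in the frame. Under
a random arrangement of organelles the two densities agree and `E ~ 1`;
the test suite verifies `E` in [0.8, 1.2] under complete spatial
randomness. Summing `pi * d^2` ignores overlap between adjacency zones;
a grid-based union-area correction is available
(`overlapCorrect = TRUE`) but off by default, since adjacency itself is
measured to the *nearest* chloroplast so no mitochondrion is ever
double-counted. Frames where every mitochondrion is adjacent
(`N - Nc = 0`), or where no chloroplast is present, have no defined
ratio and are excluded from the mean with a warning.

The cell area `A` must be supplied (e.g. from a cell-outline
measurement); when absent, `assembleCell()` falls back to the convex
hull of all mitochondrial positions, which underestimates concave cells
and is documented as a fallback, not a recommendation.

## Encounter networks and their statistics

`buildNetwork()` registers an edge between two trajectories iff they
were simultaneously present within the threshold in at least one frame
of the window; the number of such frames is kept as an annotation, but
statistics treat edges as binary (a sustained k-frame contact is one
edge). Networks only accumulate: nested windows give nested edge sets,
and lower thresholds give subsets of the 1.6 µm edge set. Both
properties are enforced by tests.

Statistics (unweighted, via igraph, each validated against an
independent Floyd–Warshall / BFS path-counting oracle):

* **mean degree** — neighbours per node, averaged over nodes. Tracks
  that never encounter anyone are isolated nodes and count in the
  denominator by default (`includeIsolated = FALSE` flips this; the
  literature is silent on the convention, so both are exposed).
* **efficiency** — mean reciprocal shortest-path length over ordered
  pairs, disconnected pairs contributing 0; 1 iff complete.
* **diameter** — longest shortest path; on disconnected graphs it is
  computed on the largest component (ties broken towards the component
  containing the smallest track id), with the component count reported
  alongside so fragmentation is never hidden.
* **mean betweenness** — endpoints excluded, tied shortest paths get
  fractional credit; both raw and `(n-1)(n-2)/2`-normalized means are
  emitted since no normalization convention is standard here.

## Group comparison protocol

Per-cell summary values (one point per cell per window) are compared
with nonparametric tests: two groups by a two-sided Wilcoxon rank-sum
test (exact when the combined n is at most 25 without ties, otherwise
the tie-corrected normal approximation; the path taken is recorded),
three or more by Kruskal–Wallis with post-hoc pairwise Dunn z-tests on
the shared pooled ranks. Benjamini–Hochberg adjustment is applied
*within* a Dunn pairwise set only — never across different summary
statistics, matching the convention of reporting each statistic's test
unadjusted across statistics.

## The synthetic-data generator

`simulateCell()` emulates the phenomenology the analysis assumes: a
population of ~50–200 mitochondria in a bounded quasi-2D domain over 120
frames spanning 233 s, mixing static, diffusive and ballistic movers,
with optional sticking/clustering and static chloroplast discs.

Defaults and their reasoning (these are plausible-for-the-system
choices, not measured values — speeds and diffusivities are not
recoverable from published boxplots):

| parameter | default | why |
|---|---|---|
| `nMito` | 100 | middle of the 50–200 per-cell range |
| `domainUm` | 60 × 60 | hypocotyl-cell scale; area 3600 µm² |
| `nFrames`, `frameIntervalS` | 120, 233/120 s | 120 frames spanning exactly the 233 s analysis window |
| `fractions` | 0.3 / 0.5 / 0.2 | most organelles diffusive, a substantial static pool, a minority in directed transport |
| `diffusionCoeff` | 0.05 µm²/s | sub-micron per-frame steps, matching visually jittery but slow wandering |
| `ballisticSpeed` | 0.4 µm/s | ~0.8 µm/frame directed runs, well below fast cytoplasmic streaming |
| `directionPersistence` | 0.9 | runs of ~10 frames before turning |
| `chloroRadiusUm` | 1.5 | typical chloroplast radius |

Mechanics worth knowing:

* Motion classes are assigned by exact largest-remainder apportionment,
  so a configured static fraction is recovered *exactly* as the
  proportion of zero-path-length tracks.
* Diffusive steps are Gaussian with per-axis variance `2 D dt`
  (mean squared step `4 D dt`; the calibration test verifies this to
  5% on ~24 000 steps).
* Boundaries reflect. Diffusive positions are mirror-folded; ballistic
  movers instead reflect their *heading* and retake the full step, so
  their per-frame displacement is exactly `v * dt` — the property the
  ballistic-limit tests assert — rather than being shortened in the
  contact frame.
* Clustering: pairs within the attraction radius merge clusters with
  `stickingProb` per frame; a cluster moves as one body, taking the
  single Brownian/ballistic update drawn for one randomly chosen member
  each frame (so clusters keep the mobility mix of their membership);
  members additionally mill inside the cluster with an independent
  Brownian jitter (`memberJitterCoeff`, default 0.01 µm²/s) and leave
  with `unstickingProb` per frame. The jitter matters: perfectly rigid
  clusters have zero internal relative motion, so clustered cells would
  never form new intra-cluster encounters — the opposite of what dense,
  dynamically milling aggregates in clustering mutants do.
* The generator is pinned to an explicit RNG
  (Mersenne-Twister/inversion/rejection) and restores the caller's RNG
  state, so identical configurations give identical cells on any
  platform.

`makeCohort()` derives per-cell seeds deterministically from a master
seed and applies per-genotype config overrides, standing in for an
imaging cohort.

### What the simulator does and does not show

Passing tests on synthetic cohorts demonstrate that the *pipeline*
recovers programmed differences in the programmed direction; they do not
validate the motion model against real cells. The simulator omits
cytoskeletal tracks, fission/fusion as topology changes, detection
gaps/noise, and any long-range transport between clusters. That last
omission has a measurable consequence: a sticky synthetic genotype
reproduces lower spacing, higher co-localization time and (marginally)
higher mean degree, but its global network *efficiency* falls, because
in this minimal model long-range network bridges are carried by free
movers and sticking converts their exploration into redundant local
edges. Real clustering mutants show *higher* efficiency, presumably
because inter-cluster transport persists there. The end-to-end cohort
test asserts the real direction for all four statistics and the
efficiency expectation fails by design — an informative negative result
about the minimal model, documented rather than patched. The mean-degree
gain is likewise small under these conditions and not significant at
every seed.

## Numerical and degenerate-input conventions

* Distance comparisons are closed (`<=`), in µm after calibration.
* Undefined statistics signal rather than silently producing numbers:
  nearest-neighbour distance with no concurrent spots, efficiency with
  fewer than 2 nodes, diameter of an edgeless graph, and enrichment
  with no chloroplasts all return `NA` with a warning; `networkSummary()`
  quiets the warnings for cohort sweeps but keeps the `NA`s.
* Canonical CSV output prints positions with 17 significant digits, so
  round-trips are bit-exact and repeated writes byte-identical.
* Problem sizes in the test suite (cells of 15–200 tracks, 10–120
  frames, cohorts of 10 cells per genotype, 200 random graphs of up to
  50 nodes) were chosen to exercise every code path at desk scale while
  keeping the full suite under a minute.

## Interfaces

The exported functions are the interface; typical flows are
`readTrackMateCsv() |> assembleCell()` or `makeCohort()`, then
`summarizeCohort()` for the tidy per-cell table, `compareCohort()` for
the statistics, and `plotCohort()` for the standard boxplot-plus-points
cohort figure. Networks export as edge lists or GraphML
(`exportNetwork()`) for external graph tools.
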