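Package: ChondrioNet
Title: Encounter Networks and Collective Dynamics of Plant Mitochondria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the collective ("social") behaviour of mitochondria
    in single plant cells from particle-tracking trajectories. Reads
    TrackMate-style spot exports, computes per-cell physical statistics
    (speed, inter-mitochondrial spacing, pairwise co-localization time,
    chloroplast-adjacency enrichment), builds time-accumulating encounter
    networks in which nodes are mitochondrial trajectories and edges are
    close approaches within a distance threshold, summarises those networks
    (mean degree, global efficiency, diameter, betweenness centrality,
    connected components), and compares genotype groups of per-cell
    summaries with nonparametric tests (Wilcoxon rank sum, Kruskal-Wallis
    with post-hoc Dunn tests and false-discovery-rate adjustment). An
    agent-based two-dimensional motion simulator generates synthetic cells
    with known ground truth (static, diffusive and ballistic movers,
    optional sticking/clustering, static chloroplasts) so the whole
    pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
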