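Package: netmet
Title: Network Pharmacology Target Prioritization and NMR Metabolomics Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating key therapeutic targets and pathways of a
    multi-component herbal preparation from protein-protein interaction (PPI)
    topology, and for discriminating treated from control metabolic profiles
    by 1H-NMR. Includes edge-list graph construction with per-component
    centrality normalization, a min-max R-statistic combining average shortest
    path length and betweenness centrality, hypergeometric gene-set
    over-representation with Benjamini-Hochberg FDR, MetPA-style pathway
    impact, spectral binning with water-region exclusion and row-sum
    normalization, NIPALS PLS-DA with 7-fold cross-validation and permutation
    testing, OPLS-DA with S-plot statistics and VIP, differential-metabolite
    calling, tripartite compound-target-metabolite network assembly, and
    seeded synthetic-data generators for PPI graphs and two-class NMR spectra.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
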