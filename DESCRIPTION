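Package: miniGCR
Title: Minisatellite Fragility, G-Quadruplex Scanning, and Fluctuation
    Analysis of Gross Chromosomal Rearrangements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the fragility of GC-rich tandem-repeat
    minisatellites assayed in the yeast gross chromosomal rearrangement
    (GCR) system. Implements per-motif and per-array sequence composition
    metrics (GC content, GC strand bias, TG/GG/GT dinucleotide bias), a
    windowed non-overlapping G-quadruplex-forming-sequence scanner for
    tandem arrays and minisatellite catalogs, Luria-Delbruck fluctuation
    assay simulation and rate estimation by the Lea-Coulson method of the
    median with Falcor-style confidence intervals, the associated
    hypothesis tests (Fisher exact, Mann-Whitney-Wilcoxon, Spearman,
    one-tailed chi-square), telomere-addition junction analysis on the
    yeast TG1-3 repeat grammar including Cdc13 consensus-site search, and
    normalised chromosome-arm position and terminal-enrichment statistics
    for minisatellite catalogs. Seeded synthetic-data generators provide
    every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Genetics, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
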