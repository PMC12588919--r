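Package: ampelomap
Title: Landmark-Based Leaf Morphometrics and QTL Mapping for Grapevine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for ampelometric analysis of grapevine
    leaves and downstream quantitative trait locus (QTL) mapping. Computes
    ten size and six shape phenotypes from 21 homologous landmarks per leaf
    (vein lengths by Euclidean distance, areas by the shoelace polygon
    formula), assembles genotype-by-attribute trait matrices across leaf
    position, daylength and year, and runs descriptive statistics
    (Kruskal-Wallis tests, Pearson correlation, principal component
    analysis, factorial variance partitioning). Reads ABH-coded F1
    genotypes with a genetic map, performs normality-gated single-locus
    genome scans with genome-wide permutation thresholds, percent variance
    explained and Bayesian credible intervals, detects QTL hotspots, and
    tests pathway enrichment in physical windows around hotspot peaks with
    one-sided Fisher exact tests. Includes seed-deterministic simulators
    for position-structured leaves and intercross genotype matrices with
    planted QTL of controlled effect size, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
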