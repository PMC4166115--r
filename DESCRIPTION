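Package: dualstress
Title: Two-Stage Mixed-Model Analysis of Dual-Stress Two-Color Microarray
    and LC-MS Metabolite Experiments
Version: 0.1.0
Authors@R: person("Plant Stress", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for a dual-stress (caterpillar versus avirulent
    bacterium) Arabidopsis experiment measured on two-color cDNA microarrays
    and by LC-MS metabolite profiling. Implements GenePix-style spot-table
    import, background/flag spot filtering, global normalization of log2
    Cy3/Cy5 ratios, duplicate-probe collapsing, a Box-Cox symmetry diagnostic,
    a two-stage mixed linear model for differential expression with
    Tukey-Kramer adjustment and Benjamini-Hochberg FDR screening, Ward
    clustering of per-probe treatment-by-time expression vectors, Eisen-style
    hierarchical clustering of treatments, internal-standard normalization and
    mixed-model analysis of LC-MS peak areas with a continuous/dichotomous
    partition, CFU-per-area and delta-CT bioassay computations, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    ape
Config/testthat/edition: 3
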