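Package: evoparallel
Title: Gene-Level Parallelism and Reciprocal Fitness in Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies parallel genetic evolution across replicate bacterial
    populations from whole-population (pooled) sequencing. Curates per-population
    mutation tables (indel consolidation, strand-aware upstream-window gene
    assignment, synonymous/multi-gene/distal-intergenic filters), builds
    populations-by-genes mutation-frequency profiles, computes Bray-Curtis,
    Jaccard, and Euclidean genetic similarity between populations, and runs
    randomization tests for within- versus between-treatment similarity and for
    shared-selection-pressure effects in a factorial design, with sequential
    Bonferroni control. Also computes competition-assay selection rates
    (Malthusian-parameter differences) and Kendall rank correlations between a
    population's genetic similarity to an environment's residents and its fitness
    there. Includes a synthetic-experiment generator emulating the statistical
    structure of a five-treatment, six-replicate evolution experiment for
    calibration, power, and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
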