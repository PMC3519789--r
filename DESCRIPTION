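Package: macromap
Title: Genome Macro-Structure Analysis on Genetic Linkage Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of the macro-structure of a genome as seen
    through a dense gene-based genetic linkage map. Provides per-chromosome
    tests of uniform gene distribution (Kolmogorov-Smirnov with the modified
    statistic whose critical values are sample-size independent), adaptive
    kernel density estimation of gene density with pointwise variability
    bands and gene-rich-region calling, detection of tandemly arrayed genes
    and a permutation test of gene-family dispersion across chromosomes,
    phylogeny-based classification of gene duplications as predating or
    postdating the gymnosperm-angiosperm split from bootstrap consensus
    trees, translocation and duplicate-distance statistics, and two-map
    synteny and collinearity analysis from reciprocal-best-hit tables.
    Seeded generators emulate every input (maps, gene-family tree sets,
    cross-species hit tables, expression matrices) with recorded ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
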