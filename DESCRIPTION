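Package: xcoex
Title: Cross-Species Co-Expression Networks from Community Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers candidate metabolic interactions in defined microbial
    communities from community RNA-seq. Gene counts are filtered and
    normalized per taxon with trimmed-mean-of-M-values scaling factors,
    variance-stabilized with a hyperbolic arcsine transform, and summarized
    to KEGG-ortholog and gut-metabolic-module level or to refined
    biosynthetic-gene-cluster sub-clusters. Within- and cross-species
    Pearson/Spearman correlations are filtered for outlier-driven
    discrepancies, scaled with a signed power adjacency, and assembled into
    a co-expression network; bootstrap resampling tests mean shifts of
    matched-module correlation sets. A seeded synthetic-community generator
    with planted cross-species interactions supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    edgeR,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
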