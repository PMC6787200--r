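Package: tadgc
Title: Sequence Composition Analysis of TADs, Chromatin Loops and Nuclear Hubs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how DNA base composition structures chromatin
    architecture. Computes windowed GC% tracks and 100-bin GC profiles of
    topologically associating domains (TADs) and loops, assigns isochore
    families from mean GC%, classifies each domain into one of six intra-TAD
    GC-gradient classes (monotone, bell, valley, half-bell, half-valley,
    flat) from per-half Pearson correlations, and verifies the classes by
    principal component analysis of the profile matrix. Derives the
    interchromosomal contact probability (ICP) of each genomic bin from a
    binned contact matrix, compares GC% between nucleolar and speckle
    interchromosomal hubs, and correlates ICP with GC%. Measures intra-TAD
    relative positions and per-100-kb densities of genes, super-enhancers and
    CTCF sites, and stratifies genes into housekeeping and tissue-specific
    sets with the tissue-specificity index Tau. A synthetic-genome generator
    with known ground truth (gradient shapes, isochore spread, hub GC shift,
    GC-contact coupling, positional feature biases, Tau structure) supports
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Matrix,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
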