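Package: xconstraint
Title: Evolutionarily Constrained Gene Expression and Splicing from Comparative RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects genes and splice junctions with evolutionarily constrained
    usage from two-species RNA-seq panels. Implements the expression dynamic-range
    (DNR) statistic with two-Gaussian mixture thresholding, non-parametric
    irreproducible-discovery-rate (npIDR) replicate filtering, intron-centric
    splicing metrics (percent-spliced-in and splicing completeness), per-gene
    decomposition of transcript-abundance variance into expression- versus
    splicing-driven components (Vls/Vt), orthologous bin-level and metagene
    chromatin-signal conservation analyses, and seeded synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
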