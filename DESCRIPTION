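Package: chipdeconv
Title: Joint Deconvolution and De-Biasing of Multi-Assay ChIP-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly analyses ChIP-seq measurements of several histone
    modifications together with their input controls to separate each assay
    into a mark-specific signal and a chromatin-bias signal shared across all
    assays on the same sample. The separation uses a three-stage constrained
    non-negative matrix factorization under a Kullback-Leibler loss; the
    shared bias is then removed from each mark by half-sibling regression on
    the log scale, yielding fold-change enrichment tracks from which discrete
    enriched regions are called. A generative simulator with full ground
    truth (Markov-chain genome layout, latent accessibility, mappability and
    non-specific-signal tracks, Poisson counts) makes the whole pipeline
    testable without external data. Includes preprocessing from aligned reads
    (fragment-length estimation by strand cross-correlation, read extension,
    library-size normalization, fixed-width binning, blacklist filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
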