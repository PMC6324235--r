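Package: ploidscan
Title: Paleopolyploidy Inference from Gene Colinearity and Ks Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and dates ancient whole-genome multiplications from gene
    order and coding sequences. Implements colinear (syntenic) block chaining
    from homolog hits, Nei-Gojobori estimation of synonymous substitution
    rates (Ks), Gaussian mixture decomposition of Ks age distributions,
    two-step evolutionary-rate correction with linear event dating against an
    outgroup calibration, dotplot-based orthology/outparalogy depth profiling
    for ploidy-level inference, reference-anchored alignment tables with
    fractionation statistics, and classification of distance-based gene-tree
    topologies distorted by post-polyploidy rate elevation. A configurable
    simulator of recursive polyploidization on a four-taxon phylogeny
    provides ground-truthed inputs in standard formats (FASTA, BED, GFF3,
    tabular BLAST).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    minpack.lm,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
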