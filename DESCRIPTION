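Package: cleavemap
Title: Cleavage-Site Discovery from 5'-End RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps target-activated ribonuclease cleavage sites from strand-specific
    5'-end RNA-seq. Reconstructs sequencing fragments from alignments, counts
    fragment 5' ends per nucleotide position and strand, and tests per-position
    enrichment of targeting over nontargeting libraries with a negative-binomial
    log-linear model (TMM normalization, Cox-Reid common dispersion, likelihood-ratio
    test, Benjamini-Hochberg correction). Calls putative cleavage sites by the
    top-100 / log2 fold-change > 4 rule, discriminates transcription start sites via
    an RppH treatment contrast, and annotates called sites with features, tRNA
    anticodon-loop profiles, sequence-logo matrices and multi-experiment
    intersections with collapsing of identical tRNA genes. Ships a synthetic-data
    generator that implants known cleavage sites and TSSs so every stage is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
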