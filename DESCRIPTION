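Package: modmotif
Title: Co-Occurrence Discovery of DNA Motifs and Motif Modules in Open
    Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers DNA motifs and motif modules (sets of motifs whose
    binding sites co-occur in significantly many short genomic regions)
    from collections of DNase I hypersensitive site (DHS) datasets.
    Provides region preprocessing and sequence masking, k-mer pattern
    ranking against a Markov background, level-wise significant-itemset
    module discovery with an exact binomial co-occurrence test, position
    weight matrix refinement, calibrated motif similarity with empirical
    E-values, cross-dataset non-redundant motif clustering, binomial
    enrichment of motifs in annotation-derived genomic region types,
    validation against known-motif collections and transcription-factor
    interaction lists, and cell/tissue-type classification from motif
    features.  A synthetic-data generator with planted ground truth
    supports end-to-end evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Matrix,
    kernlab,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
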