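Package: cfdnaflow
Title: Copy Number, Tumor Fraction and Fragmentomic Analysis of Cell-Free DNA
    from Shallow Long- and Short-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for liquid-biopsy sequencing data: binning and
    GC correction of shallow whole-genome cfDNA coverage, hidden Markov model
    copy-number segmentation and tumor-fraction estimation, fragment-size and
    fragment-end (trinucleotide motif, Gini diversity) analysis, nucleosome
    profiling of coverage around transcription start sites and control regions,
    and graft/host read assignment for xenograft plasma. Ships a labelled
    synthetic cfDNA simulator (toy references, nucleosome-periodic size mixtures,
    segmental copy-number aberrations at a configurable tumor fraction, end-motif
    bias, TSS coverage depletion, two-genome xenograft mixtures) so the whole
    pipeline is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Sequencing, Coverage, HiddenMarkovModel
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
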