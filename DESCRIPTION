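Package: allelicTx
Title: Allele-Specific Analysis of the RNA Polymerase II Transcription Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting allele-specific transcription in F1 hybrids
    from nascent-RNA (ChRO-seq/PRO-seq style) read ends. Calls single-base
    transcription start sites, clusters them into transcription start clusters
    and regions, locates promoter-proximal pause positions from RNA 3' ends,
    and tests allelic differences in abundance and shape with exact binomial
    and weighted two-sample Kolmogorov-Smirnov tests. Segments allelically
    imbalanced regions with a three-state hidden Markov model, merges them
    into strain-effect and imprinted domains across reciprocal crosses, calls
    allelic termination windows, and relates mRNA stability to changes in
    transcript primary structure. Sequence-level determinants (initiator
    dinucleotide hierarchy, TATA scoring against a first-order Markov
    background, AT content, pause-site base composition, indel offsets) are
    analysed against ascertainment-matched controls. A diploid-genome
    simulator with planted transcription-cycle truth generates allele-tagged
    read ends and mRNA counts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
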