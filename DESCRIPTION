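Package: ChromStack
Title: Stacked Chromatin-State Annotation with Multivariate Bernoulli Hidden Markov Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the full-stack ("stacked") chromatin-state annotation
    workflow: Poisson-background binarization of per-bin read counts across
    many epigenomic datasets, joint training of a single genome-wide hidden
    Markov model with independent Bernoulli emissions over all datasets,
    posterior and Viterbi segmentation of the genome into states, and
    downstream state characterization by interval fold enrichment, positional
    (anchor-relative) enrichment, gene-length-normalized average expression,
    conservation-score summaries, and cross-species state correspondence via
    segment mappings. Includes a synthetic-data generator with known ground
    truth (model, state path, planted annotations, toy gene models, toy
    cross-genome mappings) so every stage is testable end to end, plus
    information-criterion model selection over the number of states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
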