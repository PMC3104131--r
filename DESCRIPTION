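Package: cnvcall
Title: Rare Copy-Number Variant Detection from Array CGH Log2 Ratios
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-genome array comparative genomic hybridization (aCGH)
    copy-number analysis pipeline: chromosome-wise z-score standardization of
    probe log2 ratios, segmentation with a three-state Gaussian-emission
    hidden Markov model (Viterbi decoding), rule-based segment merging and
    bridging, probe-count and common-CNV filters against a control catalog,
    gene-interval annotation, trio-based inheritance labelling, and
    cohort-level rare-CNV burden statistics via Fisher's exact test. Includes
    a synthetic aCGH cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
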