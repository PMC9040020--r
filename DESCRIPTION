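Package: encap
Title: Cell Line-Specific Enhancer Prediction from DNA Sequence and
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts enhancers in a cell line-specific manner by
    integrating DNA sequence with DNase-seq chromatin accessibility.
    Provides per-position accessibility scoring from read-start counts,
    construction of length- and GC-matched negative training sets from a
    background genome, fixed-stride window augmentation with leakage-safe
    origin-level cross-validation folds, a convolutional network with
    separate sequence and accessibility feature modules joined through
    skip connections, a replicate auto-encoder that embeds a variable
    number of DNase-seq replicates into a single channel (enabling
    cross-cell-line prediction), two-stage training for imbalanced data
    with frozen feature extractors, conversion of first-layer convolution
    kernels into position weight matrices exported in MEME minimal
    format, and a synthetic-data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
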