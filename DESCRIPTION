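Package: apatail
Title: Sample-Specific Polyadenylation Site Prediction and Transcript
    3'-End Refinement from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts expressed polyadenylation (polyA) sites in a
    sample-specific transcriptome by combining DNA-sequence features
    (polyA-signal hexamers and surrounding sequence elements) with
    RNA-Seq read-coverage drop-off features over binned 3' terminal
    exons, classifies bins with a bidirectional LSTM sequence labeller,
    and rewrites transcript 3' ends into a modified GTF. Includes a
    synthetic-data generator with planted polyA-site grammar for
    end-to-end testing, precision-recall evaluation utilities for
    imbalanced bin labels, and transcriptome-level 3'-terminus
    benchmarking against 3'-seq derived site sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
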