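Package: metalign
Title: Merge an Ensemble of Multiple Sequence Alignments by Block-Wise
    Sum-of-Pairs Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines several multiple alignments of the same nucleic-acid
    sequence set into a single merged alignment whose sum-of-pairs (SP)
    score is at least as high as every input. Candidate alignments are
    validated against the unaligned reference set, recoded as gap/residue
    binary masks, partitioned into pairs of blocks holding identical
    sequence fragments by a linear two-pointer scan over cumulative
    residue counts, and the per-block SP winners are concatenated.
    Includes reference-based alignment quality metrics (aSP, Q, TC) and a
    deterministic synthetic-data generator for alignment ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
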