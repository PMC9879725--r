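Package: varalgebra
Title: A Boolean Algebra for Genetic Variants over All Minimal Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies every pair of genetic variants described against a
    shared reference sequence as exactly one of equivalent, contains,
    is-contained, overlap or disjoint by reasoning over all minimal
    alignments simultaneously. Implements the simple edit distance
    (deletions and insertions only) via a wave-based A* construction of the
    LCS-graph spanning every co-optimal alignment in linear temporary
    space, element (Psi) sets for the overlap/disjoint decision, maximal
    influence intervals as an interval prefilter for all-pairs comparison,
    and supremal delins representations for database indexing. Includes a
    parser and formatter for the genomic HGVS subset (SNV, del, ins,
    delins and bracketed alleles), a brute-force dynamic-programming
    oracle for validation, a seeded repeat-rich fixture generator, batch
    drivers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    grid,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    vcfR
Config/testthat/edition: 3
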