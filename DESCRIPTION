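Package: pocpu
Title: Percentage of Conserved Proteins (POCP and POCPu) for Bacterial
    Genus Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the percentage of conserved proteins (POCP) and its
    paralog-aware variant restricted to unique matches (POCPu) between
    pairs of bacterial proteomes, from protein FASTA files or tabular
    protein-alignment hit tables (BLAST outfmt 6, DIAMOND, MMseqs2).
    Applies the canonical conservation filter (e-value < 1e-5, identity
    > 40%, aligned region > 50% of the query length), builds within-family
    genome pair sets from a taxonomy table, and evaluates POCP/POCPu as
    genus classifiers via confusion matrices, the Matthews correlation
    coefficient, and family-specific threshold optimization.  Includes a
    built-in Smith-Waterman aligner and a synthetic proteome-pair
    generator with known ground truth so the whole stack is testable
    without external binaries or reference databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
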