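Package: wavealign
Title: Batched Pairwise Local Alignment by Anti-Diagonal Wavefronts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batched one-to-one pairwise local alignment of DNA and protein
    sequences using the Smith-Waterman algorithm with Gotoh affine gap
    penalties. The forward scoring phase sweeps anti-diagonal wavefronts and
    keeps only the two most recent diagonals plus per-column running maxima,
    so working memory is linear in the query length; alignment start
    coordinates are recovered without traceback by re-scoring the reversed
    prefixes that end at the best cell. Includes a work-partitioning batch
    driver, FASTA/FASTQ input, NCBI-format substitution matrix support
    (BLOSUM62 shipped), a synthetic pair generator, and an independent
    full-matrix oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    purrr,
    optparse,
    yaml
Config/testthat/edition: 3
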