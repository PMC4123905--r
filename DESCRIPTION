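Package: saxsearch
Title: Translated Protein Homology Search with Paired Suffix Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-and-extend protein homology search engine in the BLASTX
    family, built around a simultaneous depth-first traversal of a query
    suffix array and a database suffix array. Seeds are variable-length and
    score-thresholded rather than fixed-length: substring pairs are extended
    one residue at a time until their substitution score reaches a threshold,
    with score-gap and non-positive-score pruning rules bounding the search
    space. Seeds are refined by X-drop ungapped extension, merged by a
    same-diagonal chain filter, and finished with X-drop gapped (affine)
    extension. Supports six-frame translation of DNA reads, database chunking
    for bounded memory, BLAST tabular output, and a synthetic planted-homolog
    fixture generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
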