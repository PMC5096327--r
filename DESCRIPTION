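Package: dbblastp
Title: Database-Indexed Protein BLAST Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein sequence similarity search against a database-indexed,
    length-sorted and block-partitioned protein database. Builds a blocked,
    sorted, delta-compressed inverted index over database words with
    neighbor-word indirection, and searches it with two-level hit binning,
    filtered two-hit ungapped extension, and gapped X-drop extension with
    traceback. Alignments are scored with BLOSUM matrices and assessed with
    Karlin-Altschul statistics. Includes a synthetic protein database
    generator with planted homologies and brute-force reference
    implementations (Smith-Waterman, query-indexed two-hit scan) used as
    test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
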