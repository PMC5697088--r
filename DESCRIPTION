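Package: seqsieve
Title: Batch Protein Homology Search over Compressed and Clustered Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine batch searching for protein homology. A protein
    database and a query set are losslessly compressed by removing locally
    redundant subsequences and recording difference scripts; the compressed
    database is indexed by score-thresholded keys in a ten-letter reduced
    amino-acid alphabet, ten-residue seeds are clustered by Hamming distance
    around representative seeds, and query seeds are matched against cluster
    representatives with a triangle-inequality compensation filter. Matching
    seeds are extended into hits, the implicated original sequences are
    reassembled from the difference scripts into a small execution database,
    and a native Smith-Waterman fine search with Karlin-Altschul E-values
    produces the final ranked homology report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
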