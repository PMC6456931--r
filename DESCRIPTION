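Package: groupseed
Title: Grouped Short k-mer Seeding for Sensitive Long-Read Overlap Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: All-vs-all overlap detection for error-prone long reads
    (PacBio/ONT-like, indel-dominated errors) using groups of short k-mer
    hits that satisfy statistically calibrated distance constraints.
    Candidate read pairs are filtered by positional shared k-mer counts
    computed from a generalized suffix array with LCP and read-id arrays;
    surviving pairs are seeded with short exact matches clustered into
    group seeds under waiting-time and random-walk derived thresholds,
    chained by sparse dynamic programming, and accepted by a
    matched-bases significance rule. Includes a synthetic long-read
    simulator with exact ground-truth overlaps and an evaluation harness
    (sensitivity, precision, F1, overlap-size-binned sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
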