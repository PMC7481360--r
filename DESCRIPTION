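Package: acetoscan
Title: Functional-Gene Amplicon Profiling of Acetogenic Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained analysis pipeline for single-end amplicon reads of
    the formyltetrahydrofolate synthetase (FTHFS) marker gene, used to profile
    potential acetogens in anaerobic microbial communities. Covers degenerate
    primer trimming and quality filtering, dereplication, de novo two-parent
    chimera flagging, greedy centroid OTU clustering, six-frame translation
    with best-reading-frame selection, translated local search against a
    protein reference database with E-value filtering and taxonomic
    assignment, neighbor-joining phylogeny with bootstrap supports, and
    rank-collapsed abundance and diversity summaries. Includes a synthetic
    mock-community generator that provides ground truth for every pipeline
    stage without any external database.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
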