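Package: hybridscreen
Title: Clone Assembly and Mutation Mapping for Yeast Two-Hybrid Sanger Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Sanger sequencing products from yeast two-hybrid
    (Y2H) and reverse two-hybrid (RY2H) screens. Trims low-quality (N) ends
    and vector tag sequences with mismatch tolerance, translates reads with
    IUPAC-ambiguity handling, detects reading frames, assembles paired
    forward/reverse sequencing products of each clone by strict local
    alignment, identifies clones against a local protein database, and maps
    and summarizes interaction-defective mutations against a reference
    model sequence. Includes a synthetic screen simulator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'hybridscreen-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'align.R'
    'translate.R'
    'cleanup.R'
    'assemble.R'
    'identify.R'
    'modelmap.R'
    'seqio.R'
    'pipeline.R'
    'simulate.R'
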