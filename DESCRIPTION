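Package: tcrtag
Title: Tag-Based T-Cell Receptor Annotation and UMI Error Correction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates T-cell receptor (TCR) rearrangements from repertoire
    sequencing reads by exact germline tag matching with an Aho-Corasick
    keyword trie, corrects PCR and sequencing errors by clustering reads on
    unique molecular identifiers (UMIs) and dominant receptor sequences under
    Levenshtein thresholds, reconstructs and translates CDR3 junctions, and
    writes AIRR Community rearrangement tables. A repertoire, PCR and
    sequencing simulator supports benchmarking of annotation accuracy and
    recovery of pre-amplification molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
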