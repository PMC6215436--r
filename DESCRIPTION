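Package: dmienrich
Title: Domain-Motif Interaction Enrichment in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("DMI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how well a protein-protein interaction (PPI) dataset
    captures domain-motif interactions (DMIs). Known or predicted short linear
    motif (SLiM) occurrences, motif-domain interaction annotations and protein
    domain compositions are combined under one of three mapping strategies of
    decreasing stringency to enumerate the potential DMIs in a PPI network.
    The subset realised by observed interactions ("predicted DMIs") is compared
    against a degree-preserving permutation null obtained by shuffling the
    domain-side protein column without introducing redundant pairs, yielding an
    empirical enrichment p-value, an enrichment ratio, a per-DMI false
    discovery rate and a normalised-D distribution. Includes a noise-injection
    robustness analysis, a synthetic fixture generator for end-to-end testing,
    and a command-line interface with CSV, histogram and GraphML outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
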