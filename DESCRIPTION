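Package: sigentropy
Title: Signaling Entropy of Expression-Weighted Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes global signaling entropy (SR) and per-gene local
    signaling entropy (LSR) from a protein-protein interaction network
    weighted by gene expression via mass action, together with the
    downstream analyses that use them: differential LSR between tumor and
    normal samples (Student's t, FDR, Cohen's d), consensus feature
    selection across cancer types, hypergeometric over-representation
    against user-supplied gene sets, sample stratification by clustering,
    Cox proportional-hazards survival modelling on LSR features with
    median-split risk groups, and drug-response scoring via the LSR ratio
    of drug targets. A synthetic-data module generates scale-free
    interaction graphs, two-group expression with planted effects,
    survival times with known hazards, and drug panels with known
    IC50-ratio coupling, so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    survival,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
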