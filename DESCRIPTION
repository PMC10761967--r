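Package: orthoscreen
Title: Comparative Divergence Screening of Ortholog Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens ortholog groups for lineage-specific acceleration of
    protein evolution. Builds pairwise percent-identity matrices from global
    affine-gap alignments, computes the Identity Ratio (IR) and Extended
    Identity Ratio (EIR) statistics with Tukey interquartile outlier fencing,
    compares selected-site rates between exon partitions with a two-proportion
    z-test, and provides a counting-method (Nei-Gojobori 1986) dN/dS estimator
    with Jukes-Cantor correction. Includes a sequence-evolution simulator over
    a species tree with per-branch rate multipliers and per-site selection
    classes, so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
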