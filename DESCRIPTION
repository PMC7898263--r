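Package: mammaging
Title: Consensus Differential Expression and Composition Analysis for
    Aging Mammary Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for young-versus-aged single-cell RNA-seq
    atlas analysis of the mouse mammary gland: cell-level quality-control
    filtering, marker-based cell typing with module scoring and cell-cycle
    phase calls, one-vs-each cell-type signature derivation, a
    three-criteria consensus differential-expression procedure combining a
    Wilcoxon rank-sum engine with a zero-inflation-weighted negative
    binomial engine, compositional shift testing with Fisher's exact and
    chi-square tests, and hypergeometric gene-set over-representation
    analysis. Ships a synthetic atlas generator with ground truth that
    emulates the statistical structure of a two-age-group 10x Genomics
    experiment, so every stage is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
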