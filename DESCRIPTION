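Package: blastoHet
Title: Transcriptomic Heterogeneity Analysis of Preimplantation Blastomeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter-blastomere transcriptomic heterogeneity in
    cleavage-stage (2-, 4- and 8-cell) embryos from single-cell RNA-seq counts.
    Provides a negative-binomial simulator of blastomere counts with planted
    stage programs and differentiating subpopulations, QC and TPM
    normalization, cell-cell Pearson correlation clustering with 1 - r
    distance, consensus classification of blastomeres into embryonic and
    differentiating subpopulations, CV-squared overdispersion trend fitting
    (a1/mu + a0) for variable-gene calling, differential-expression and
    hypergeometric overlap tests, gene-set over-representation with a
    multi-cutoff consensus rule, and minimum-spanning-tree pseudotime
    trajectories with branch detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
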