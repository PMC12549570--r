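Package: rfpeptidome
Title: Affinity-Enriched Rheumatoid Factor Peptide Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-acquisition analysis of affinity-enriched rheumatoid
    factor LC-MS/MS peptide data: reconciliation of database-search and
    de novo identifications, allocation of peptides to immunoglobulin
    constant regions (isotype-level quantification with positivity
    cut-offs) and to variable-region framework/CDR segments by local
    alignment against IMGT-numbered germline references, robust
    median/MAD abundance normalization, Kruskal-Wallis/Dunn differential
    testing with Holm-Sidak adjustment and fold-change calling, sparse
    PLS discriminant analysis with cross-validated stability selection
    of discriminative peptides, and cross-experiment matching of LC-MS
    features by m/z, retention time and charge.  A synthetic cohort
    generator with in-silico Lys-C/chymotrypsin digestion reproduces
    the data structure the analysis assumes, with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, ImmunoOncology, Software
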