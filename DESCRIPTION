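Package: devoTAI
Title: Evolutionary Transcriptome Indices Across Developmental Stages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phylo-transcriptomic analysis of ordered developmental
    series. Computes expression-weighted evolutionary indices (transcriptome
    age index TAI, nonsynonymous and synonymous divergence indices TdNI and
    TdSI, codon-bias index TCBI), their cumulative-phylostrata and min-max
    normalized variants, per-phylostratum relative expression, and Wright's
    effective number of codons. Builds gene-age (phylostratum) maps from
    homology hit tables with e-value robustness sweeps, tests profile shape
    with a permutation flat-line test, and performs stage-wise two-sided
    hypergeometric functional enrichment with Benjamini-Hochberg correction.
    Includes a negative-binomial synthetic-data generator with known ground
    truth (gene ages, hourglass effect size, divergence-age coupling) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Phylogenetics, Sequencing
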