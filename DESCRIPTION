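Package: crossens
Title: Cross-Species Comparative Transcriptomics of the Colonic Enteric Nervous System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing colonic enteric nervous
    system transcriptomes between species (pig and human). Covers selection of
    high-quality 1:1 orthologs from scored homology tables, RPKM computation and
    median-scaling cross-species normalization anchored on rank-conserved genes,
    distributional similarity testing (ECDF, Kolmogorov-Smirnov, chi-squared,
    Spearman), over-representation analysis with term-specificity filtering,
    enrichment-map construction with a functional-linkage-coverage statistic,
    WikiPathway scoring by harmonic-mean p-value combination and enrichment
    ratios, single-cell quality control, marker finding, ligand-receptor
    interaction calling, and an exact-binomial calculator for the number of
    cells required to capture rare cell types. A synthetic-data generator with
    recorded ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
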