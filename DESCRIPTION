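Package: gmdr
Title: Generalized Multifactor Dimensionality Reduction for Gene-Gene Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) in SNP association data
    with the generalized multifactor dimensionality reduction (GMDR) method.
    Per-subject score statistics (generalized linear model residuals) adjust
    binary, quantitative or count phenotypes for covariates; multi-SNP genotype
    cells are classified as high- or low-risk under K-fold cross-validation;
    candidate interaction models are ranked by score-weighted balanced accuracy
    and retained by cross-validation consistency; significance is assessed by a
    permutation test of the averaged testing accuracy.  Includes SNP quality
    control (missingness, minor allele frequency, exact Hardy-Weinberg test),
    a physical-distance filter, a staged two- to five-way search with core-SNP
    detection, PLINK text and matrix-TSV input, and a synthetic-data generator
    with known planted interaction structure.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
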