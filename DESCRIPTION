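Package: cdmr
Title: Causal Direction Inference Between Two Traits from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers both the existence and the direction of a causal
    relationship between two traits from two independent GWAS summary
    datasets, using ratios of SNP-trait Pearson correlations across
    multiple, possibly LD-correlated, genetic instruments. Provides the
    CD-Ratio generalized least squares estimator, the pleiotropy-robust
    CD-Egger and CD-GLS random-intercept estimators, a multivariable
    extension adjusting for a third trait, a bi-directional extension,
    chi-squared goodness-of-fit tests, the single-SNP Steiger
    directionality test with multi-SNP aggregation, rank-sum based
    instrument selection with LD pruning, and a synthetic-data simulator
    for two-cohort marginal GWAS scans under configurable pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
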