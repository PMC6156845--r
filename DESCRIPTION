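Package: pusat
Title: Pedigree-Based Unified Score Association Tests for Multiple
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint association tests of a genetic variant with multiple
    correlated quantitative traits in samples with family structure.
    Implements marginal linear mixed models with a kinship random effect
    (REML via eigendecomposition of the relatedness matrix), the
    sum-of-squared-score (SSU) test with the Liu et al. moment-matched
    chi-square approximation, a matrix-variate multivariate linear mixed
    model fitted by EM, and the unified score-based association test
    (USAT) and its pedigree-based extension (pUSAT): a min-p combination
    of the MANOVA-type and SSU statistics over a weight grid, with a
    numerical-integration p-value. Includes PLINK bed/bim/fam input and
    output, variant and sample quality control (call rate, minor allele
    frequency, Hardy-Weinberg equilibrium), empirical and pedigree
    relatedness matrices, a gene-dropping family simulator with
    matrix-variate normal phenotypes, and a seeded Type I error harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
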