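Package: stratspectrum
Title: Allele-Frequency-Stratified Population Structure and Association Test Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how population stratification differs across the
    allele frequency spectrum (common, low-frequency and rare variants) and how
    it affects case-control association tests. Provides a Balding-Nichols
    generator of region-structured genotype cohorts with a controllable minor
    allele frequency spectrum and region-differential case sampling; PLINK
    text and binary genotype input/output with call-rate and exact
    Hardy-Weinberg quality control; MAF categorization, rare-allele burden and
    regional sharing statistics with an exact expected-sharing computation;
    the lambda_r overdispersion coefficient for stratified homogeneity tests;
    LD pruning, frequency-weighted principal component analysis,
    cross-category PC correlation and supervised ancestry assignment by EM;
    and per-variant association scans (Armitage trend, PC-adjusted,
    Cochran-Mantel-Haenszel, mixed-model) summarized by genomic-control
    inflation per frequency category.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
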