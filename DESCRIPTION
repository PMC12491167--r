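Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation and Drug-Target
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: reading, validation and effect-allele
    harmonization; instrument selection (exposure p-value, minor allele
    frequency, greedy LD clumping, outcome-association policy,
    F-statistic); causal-effect estimation by Wald ratio, inverse-variance
    weighting, MR-Egger, weighted median and mode-based estimators;
    sensitivity diagnostics (Cochran's Q, leave-one-out, Egger intercept,
    Steiger directionality, analytic power); two-step MR mediation
    decomposition by the product-of-coefficients method; summary-data-based
    MR (SMR) with the HEIDI heterogeneity test for eQTL-based drug-target
    validation; and a generator of aligned exposure/mediator/outcome
    summary statistics with known causal structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
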