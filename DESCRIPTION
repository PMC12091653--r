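Package: medmr
Title: Two-Step Mendelian Randomization Mediation with Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-sample Mendelian randomization from GWAS summary statistics,
    organised around a lipid -> plasma-protein -> disease mediation chain.
    Provides instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering), allele harmonization with palindromic-variant
    handling, five causal estimators (inverse-variance weighted in fixed and
    multiplicative-random-effects modes, MR-Egger, weighted median, maximum
    likelihood) with Cochran Q heterogeneity and Egger-intercept pleiotropy
    diagnostics, summary-data-based MR (SMR) with the HEIDI heterogeneity test
    on top cis-pQTLs, Bayesian colocalization via per-variant approximate Bayes
    factors over hypotheses H0-H4, and product-of-coefficients mediation with
    delta-method standard errors and mediated-proportion confidence intervals.
    A seeded synthetic-data generator (LD-block reference panels, a
    quantitative exposure -> quantitative mediator -> binary outcome causal
    chain, per-variant marginal summary statistics) makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
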