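Package: relsens
Title: Test-Retest Reliability and Sensitivity of Strength and Power Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for test-retest reliability and sensitivity analysis of
    repeated strength and power measurements (isometric maximal voluntary
    contractions, countermovement jumps, reactive hops). Collapses trial-level
    data to session scores (average, highest, or lowest value), computes
    two-way absolute-agreement intraclass correlations ICC(2,1)/ICC(2,k) with
    F-based 95% confidence intervals and Koo-Li classification, within-subject
    coefficients of variation, and repeated-measures ANOVA tests for systematic
    bias, then derives the sensitivity chain: standard error of measurement
    (SEm), smallest worthwhile change (SWC), and minimal difference (MD).
    Includes a variance-components simulator that emulates a multi-session
    test-retest study design for validation and power analysis, and published
    reference tables from a nine-week study for cross-checking the arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
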