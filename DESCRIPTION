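Package: asymclr
Title: Asymmetric Integration of Matched Case-Control Cohorts with
    Conditional Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic association testing for 1:1 matched case-control cohorts
    with data-adaptive borrowing of strength from auxiliary cohorts. Fits
    conditional logistic regression on within-stratum allele-dosage
    differences, assigns each auxiliary cohort a weight in [0,1] through a
    two-parameter map of per-cohort relevance p-values chosen to minimise a
    leave-one-out cross-validated likelihood, and controls the false
    discovery rate of the resulting (anti-conservative) integrated p-values
    with a single-iteration within-stratum permutation procedure. Includes
    LD clumping of significant variants, transcription-start-site proximity
    enrichment testing, a multi-cohort synthetic-data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
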