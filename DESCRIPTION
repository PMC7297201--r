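Package: chronoprs
Title: Polygenic Risk Profile Scores, Illness Chronicity, and Case-Control
    Prediction Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how genomic risk profile scores (GRPS, also
    known as polygenic risk scores) relate to illness chronicity in ascertained
    case-control samples, and how enriching cases by chronicity or stratifying
    by sex changes case-control prediction accuracy. Provides a
    liability-threshold simulator for a discovery GWAS plus an ascertained
    target cohort with register-style chronicity markers, allele-aligned
    p-value-thresholded score computation, case-only association models of
    follow-up-adjusted admission rates, incremental Nagelkerke pseudo-R-squared
    for nested logistic models, matched-subsample permutation tests of
    enrichment, and a sex prediction-gap permutation test, with a seeded
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
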