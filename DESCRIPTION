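Package: rxagsp
Title: Relative Expression Analysis with Gene-Set Pairs for Survival Screening
Version: 0.1.0
Authors@R: person("rxagsp", "developers", email = "rxagsp@example.org", role = c("aut", "cre"))
Description: Screens pairs of biologically pre-defined prognostic gene sets
    (a "poor-prognosis" set and a "good-prognosis" set) against multi-cohort
    expression and survival data. Each patient receives a rank-free
    individualized index -- the median expression of the poor-prognosis
    members minus the median of the good-prognosis members -- whose sign
    dichotomizes the cohort. Candidate gene-set pairs are evaluated per
    cohort by log-rank tests and Cox proportional-hazards models, combined
    across cohorts with the weighted Liptak-Stouffer method under Bonferroni
    control, and the winning pair is validated with an empirical resampling
    null built from size-matched random gene sets. Companion tools cover
    probe-to-gene collapsing, Freeman-Halton exact association tests of the
    resulting grouping with clinical covariates, promoter scanning with
    position weight matrices, and a seeded multi-cohort simulator with a
    planted index-hazard link.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
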