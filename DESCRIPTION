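Package: coxcpt
Title: Change-Point Cox Models for New-User Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative-effectiveness analyses of treatment
    initiators in administrative claims data when the proportional-hazards
    assumption fails for the treatment variable. Implements new-user,
    active-comparator cohort construction from claims-like tables; detection
    of a hazard-ratio change point by maximising the median of bootstrap
    partial likelihoods of a univariate time-split Cox model over a monthly
    grid of candidate cut-off times; two-period hazard-ratio estimation with
    nested covariate adjustment; Mantel-Haenszel age- and sex-adjusted event
    rates; inverse-probability-of-treatment-weighted sensitivity analyses;
    and a synthetic claims generator with known piecewise-constant treatment
    effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
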