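Package: xcimosaic
Title: Survival Estimation and Simulation for X-Inactivation Mosaic Tissues
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-count data from X-chromosome-inactivation
    (XCI) mosaic tissues carrying an X-linked fluorescent reporter. Implements
    the reciprocal-fraction estimator of the survival probability of
    reporter-negative (mutant-X-active) cells from observed GFP-positive
    fractions, with per-animal aggregation, one-way misclassification
    correction and bootstrap uncertainty; a stochastic simulator of mosaic
    cohorts (clonal founder pools, staged cell-autonomous elimination, a
    tissue-level cell-competition penalty, and counting noise); a staged
    survival model for postnatal trajectories of reporter positivity; a
    uniform-versus-mosaic contrast that recovers the competition coefficient;
    and the two-sample testing protocol (Shapiro-Wilk gate, Student's t,
    asterisk significance tiers) used to compare cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
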