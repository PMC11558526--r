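Package: immunostage
Title: Stage-Specific Immuno-Assessment of Sepsis from Longitudinal Blood Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-reductionist immunophenotyping of septic patients from
    serial complete blood counts. Expands leukocyte differentials into a
    combinatorial space of dimensionless indicators (ratios and products of
    ratios), quantifies between-group data overlap as an interval-intersection
    index, detects thin line-like structures and perpendicular inflections in
    three-dimensional indicator space, classifies every observation into one of
    five inflammatory stages (early inflammation, early immunocompetence,
    intermediary suppression, late suppression, other) from cohort-quantile rules
    on the neutrophil/lymphocyte ratio, its monocyte-adjusted form, and serum
    urea and creatinine, and tracks personalized temporal trajectories against
    the population reference. Includes a seeded generator of stage-structured
    longitudinal synthetic cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
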