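Package: chemopanel
Title: Gene-Panel Discovery for Chemotherapy Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers a fixed-size gene expression panel predictive of
    chemotherapy response from cell-line expression and drug-efficacy data,
    and transfers the panel to patient cohorts for survival stratification.
    Cell lines are split into low/medium/high response tertiles by drug
    activity area, genes are screened with a Kruskal-Wallis rank test, and a
    genetic-algorithm wrapper selects the panel that maximizes leave-one-out
    cross-validated accuracy of a multiclass support vector machine. Panel
    significance is assessed against an empirical permutation null of random
    gene subsets. Validation utilities z-score cohort expression, classify
    patients into response groups, and run Kaplan-Meier/log-rank and Cox
    proportional-hazards analyses, including Schoenfeld sample-size planning.
    Seeded synthetic-data generators emulate the cell-line and patient-cohort
    inputs so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    survival,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
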