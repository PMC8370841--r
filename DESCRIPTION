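Package: PGxCohort
Title: Pharmacogenomics-Guided Cohort Analysis of Treatment Effectiveness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacogenomics-guided analysis of treatment
    effectiveness in psychiatric cohorts. Implements a 54-gene / 104-variant
    pharmacogenomic test panel, star-allele based CYP2D6 and CYP2C19
    metabolizer phenotyping, a composite genetic mutation score (0-15)
    combining pharmacokinetic phenotypes with pharmacodynamic variant burden,
    a questionnaire-derived treatment-effectiveness score (1-10), and the
    accompanying cohort statistics: paired Wilcoxon signed-rank test with
    effect size r, Spearman rank correlation, and a bootstrap-smoothed ROC
    curve. A calibrated, seeded synthetic-cohort generator allows the whole
    pipeline to be exercised end to end without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Pharmacogenomics, Pharmacogenetics, StatisticalMethod, Software
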