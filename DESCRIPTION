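Package: voctraj
Title: Biomarker and Vital-Sign Trajectories During Sickle-Cell
    Vaso-Occlusive Crisis Hospital Stays
Version: 0.1.0
Authors@R:
    person("voctraj", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to describe the course of routinely collected biomarkers
    and vital parameters during hospital stays for non-complicated
    vaso-occlusive crisis (VOC) in sickle-cell disease.  Provides
    warehouse-style cohort selection with ordered inclusion/exclusion
    filters and a flowchart report, penalized B-spline estimation of
    averaged trajectories with cluster-bootstrap pointwise confidence
    bands for irregularly sampled longitudinal measurements,
    threshold-window proportion analysis, baseline-characteristics
    ("table one") group comparisons with exact Fisher, chi-squared and
    Wilcoxon rank-sum tests implemented from first principles, and a
    seedable synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
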