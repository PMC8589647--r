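Package: brainpad
Title: Normative Brain-Age Models and Brain-PAD Case-Control Analysis
    for Multi-Site Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mega-analytic brain-age studies on pooled multi-site
    FreeSurfer morphometry. Fits sex-specific normative ridge-regression
    brain-age models on regional volumes, cortical thickness, surface area
    and intracranial volume, computes the brain-predicted age difference
    (brain-PAD), and performs case-control and clinical-subgroup inference
    with scanning-site random intercepts, age-bias covariates, Cohen's d
    effect sizes and false-discovery-rate control. Includes a calibrated
    synthetic multi-site cohort generator, site-stratified train/test
    partitioning, hemisphere averaging and outlier QC, model serialization,
    and model-interpretation analyses (structure coefficients, modality
    perturbation, single-modality models), plus an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
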