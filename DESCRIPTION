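Package: clinage
Title: Biological Age Estimation from Clinical Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates biological age from routinely collected clinical
    biomarkers using the Klemera-Doubal method (KDM1), multiple linear
    regression, and the Levine phenotypic-age formula. Provides biomarker
    screening and preprocessing (Box-Cox normalisation, winsorisation,
    gender adjustment, redundancy and age-collinearity checks), case-control
    matching, derived aging metrics (delta age and age ratio) with
    group comparisons, and validation of delta age against time-to-event
    outcomes via Cox proportional-hazards models and Kaplan-Meier curves.
    Includes a synthetic cohort generator reproducing the statistical
    structure these estimators assume, so the whole pipeline can be
    exercised and power-checked without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    foreign,
    jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
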