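Package: hipshape
Title: Statistical Shape Modelling of Infant Hip Ultrasound Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for two-dimensional statistical shape analysis of
    the infant acetabulum from ultrasound landmark annotations. Builds a point
    distribution model over a 13-point ilium-acetabulum contour protocol
    (generalized Procrustes alignment followed by principal-component shape
    modes retained to 95% of variance), scores hips as per-mode Z-scores,
    computes a geometric femoral-head-coverage percentage with Morin
    categorization, derives treatment outcomes, fits univariable and
    multivariable logistic-regression association models (odds ratios, Wald
    confidence intervals, likelihood-ratio omnibus tests, quintile-categorized
    variants), and quantifies annotation reliability with a variance-weighted
    two-way absolute-agreement intraclass correlation. A synthetic-cohort
    generator with known ground truth (planted orthogonal shape modes, landmark
    and re-annotation noise, logistic outcome links) makes every stage testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
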