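Package: hipshape
Title: Statistical Shape Modelling of the Hip and Association with Radiographic Osteoarthritis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dual-energy X-ray absorptiometry (DXA) based
    hip shape analysis: generalized Procrustes alignment of 58-point hip
    landmark configurations, a principal-component point-distribution model
    ("hip shape modes") with per-mode scores in cohort standard-deviation
    units, construction of radiographic hip osteoarthritis outcomes (Croft
    grade from component scores for osteophytes, joint space narrowing,
    sclerosis, cysts and femoral head deformity) and hip pain outcomes, and
    covariate-adjusted logistic and proportional-odds regression reporting
    odds ratios per SD of each shape mode. Ships a synthetic cohort generator
    with planted cam- and pincer-type deformity fields and known effect
    sizes so every stage is testable end to end without participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
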