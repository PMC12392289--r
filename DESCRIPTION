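Package: visreb
Title: Simulation and Analysis of Viscoelastic-Response Ultrasound
    Elastogram-to-B-Mode Ratios in Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for studying the elastogram-to-B-mode diameter
    ratio (E/B) in acoustic radiation force impulse (ARFI) ultrasound of
    breast lesions.  Simulates two-dimensional viscoelastic lesion
    phantoms with class-conditional margin mechanics, forward-models
    double-push ARFI displacement responses with a Voigt
    (mass-spring-damper) tissue model, synthesizes radio-frequency
    speckle and recovers motion by normalized cross-correlation,
    assembles co-registered peak-displacement (PD), relative elasticity
    (RE) and relative viscosity (RV) parametric images with depth and
    elasticity corrections, measures elastogram-to-B-mode diameter
    ratios with an automated endpoint rule, and evaluates
    logistic-regression lesion classifiers with ROC, correlation and
    rank-sum statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
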