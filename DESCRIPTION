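Package: qtcaudit
Title: Audit of Automated QTc Measurement Against the Manual Tangent Method
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how automated electrocardiograph QTc readings
    diverge from manual tangent-method measurement. Provides a seeded
    multi-lead synthetic ECG generator with analytically known fiducials
    (gaussian-deflection beat templates, sinus/AF/ectopic rhythms, bundle
    branch block, artifact and U-wave morphology), an algorithmic
    implementation of the manual QT protocol (tangent-method T-wave end,
    lead II/V5 primary-lead rule, five-beat averaging in atrial
    fibrillation, post-ectopic and bigeminy exclusions), a stylized
    emulator of machine QT measurement (all-lead superimposition, Bazett
    correction without QRS-duration adjustment), sex-specific long-QT
    classification, and the downstream diagnostic-accuracy analysis
    (sensitivity, specificity, PPV/NPV with Wilson intervals, inter-reader
    agreement, and logistic-regression predictors of false-positive
    long-QT calls).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
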