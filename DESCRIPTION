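Package: pepscreen
Title: Robust Reactive-Peptide Detection from Peptide Microarray Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for antibody reactivity
    screening on peptide microarrays. Reads GenePix Result (GPR/ATF)
    quantification tables, stabilizes variance with a binary-log
    transform, removes systematic array effects (subarray, print needle,
    row, column) with a linear model fitted on dedicated control
    peptides, optionally flags unreliable spots with a random-forest
    classifier trained on replicate-regression confidence bands,
    excludes peptides that bind the labelled secondary antibody using a
    two-component Gaussian mixture fitted on sample-free (empty) slides,
    and calls reactive peptides probabilistically from the fitted noise
    component. Includes an evaluation module (sensitivity, specificity,
    accuracy with bootstrap confidence intervals) and a synthetic-slide
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
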