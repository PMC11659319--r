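Package: abrcog
Title: Auditory Brainstem Response Biomarkers for Cognitive Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking auditory brainstem response (ABR)
    wave features to cognitive performance in adults: epoch-level artifact
    rejection, zero-phase bandpass filtering and averaging, windowed wave
    I/V peak picking, pure-tone-average and cognitive composite scoring,
    age-adjusted linear association models, percentile-criterion ROC/AUC
    sweeps with Youden-optimal cutoffs and a random-predictor chance band,
    and k-fold cross-validated single-feature linear discriminant
    classification. Includes a synthetic cohort and ABR epoch generator
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    lmtest,
    car
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    readxl,
    withr
Config/testthat/edition: 3
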