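Package: acrodat
Title: Disease Activity Assessment in Acromegaly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a composite disease-activity system for acromegaly:
    mapping of raw clinical measurements (IGF-I, tumor status on MRI,
    comorbidities, the five-item Signs and Symptoms Score, and the 22-item
    AcroQoL questionnaire) to three-level severity grades; enumeration and
    indexing of the 243 (3^5) hypothetical patient scenarios used in
    clinician validation surveys; inter-rater agreement statistics
    (per-scenario pairwise agreement, category proportions, Fleiss' kappa)
    on rater-by-scenario tables; and the disease-activity algorithm itself,
    combining a non-compensatory gate on IGF-I and tumor status with a
    two-stage logistic probability model and a continuous 0-1 activity
    score. A latent-variable rater simulator with closed-form truth makes
    every stage testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
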