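Package: osteoclaims
Title: Treatment-Pattern and Adherence Analysis of Osteoporotic-Fracture
    Hospital Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort construction, baseline characterization (Charlson
    comorbidity index, activities of daily living), three-phase
    antiosteoporotic treatment classification, refill-gap episode analysis
    (discontinuation, switching, restarting, augmentation), medication
    possession ratio adherence, and multivariable logistic regression of
    treatment receipt for hospital-claims data on osteoporotic fracture.
    Includes a calibrated synthetic claims generator that emulates the
    record structure of Japanese DPC hospital databases so the full
    pipeline can be exercised and validated without access to proprietary
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
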