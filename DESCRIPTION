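Package: petflare
Title: Early Metabolic Response and Bone-Flare Assessment for
    FCH-PET/CT-Monitored Abiraterone Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for early treatment-response assessment in metastatic
    castration-resistant prostate cancer monitored with 18F-fluorocholine
    PET/CT. Classifies follow-up scans into CR/PR/SD/PD from percent
    changes in lesion SUVmax, computes PSA response endpoints (maximal
    decline, >=50% responder status, PSA flare), applies a multi-timepoint
    bone-flare procedure that reclassifies early metabolic progression
    using PSA, CT and a confirmatory PET scan, derives PSA-vs-PET
    agreement statistics with exact confidence intervals, and links early
    classification to progression-free and overall survival via
    Kaplan-Meier and Cox proportional-hazards models. A synthetic-cohort
    generator with latent response classes makes every stage runnable and
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
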