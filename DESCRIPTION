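Package: ckdprev
Title: Multi-Source Case Ascertainment and Prevalence Estimation for
    Chronic Kidney Disease from Administrative Health Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies prevalent chronic kidney disease (CKD) cases by
    record linkage across four administrative health registries (hospital
    discharges, ticket exemptions, outpatient specialist services, drug
    dispensings), with ICD-9-CM/ATC wildcard code matching, an acute renal
    failure exclusion rule, severity stratification, age- and sex-specific
    and directly standardized prevalence rates with confidence intervals,
    source-contribution accounting, and validation of dialysis
    ascertainment against a gold-standard registry. Includes a synthetic
    registry generator with plantable ground truth so the whole pipeline
    is testable without access to real person-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
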