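Package: hipfraclink
Title: Linked Versus Unlinked Hospital Discharge Data for Incident
    Fall-Related Hip Fracture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how episode-level ("unlinked") hospital
    discharge data bias incidence and comorbidity estimates for
    fall-related hip fracture in community-dwelling older people,
    relative to person-level ("linked") data.  Provides a synthetic
    episode-of-care generator with ground truth, stepwise deterministic
    record linkage with quality scoring, incident-case selectors
    (a linked reference standard with a 120-day clearance period and an
    external-cause disagreement rule, and five unlinked selection
    scenarios), Deyo-Charlson comorbidity ascertainment with
    condition-onset filtering and person-level lookback, and evaluation
    utilities (sensitivity/specificity/PPV/NPV with confidence
    intervals, overestimation, proportion tests, age-specific and
    directly standardised admission rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
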