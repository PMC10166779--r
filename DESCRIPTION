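Package: lynchrisk
Title: Prospective Cancer Risk, Survival and Mortality Estimation in
    Lynch Syndrome Surveillance Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation pipeline for prospective surveillance cohorts of
    mismatch repair (MMR) pathogenic variant carriers (Lynch syndrome):
    person-year attribution over five-year age bands with left truncation,
    annual incidence rates by gene, sex and organ, Nelson-Aalen cumulative
    cancer incidence with Poisson-based confidence intervals, crude
    post-diagnosis survival, organ-specific crude mortality to age 75, median
    age of cancer onset by conditional-risk interpolation, and death
    tabulations.  Includes a piecewise-constant-hazard cohort simulator with
    closed-form ground truth so the whole pipeline can be exercised and
    calibrated without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    survival,
    jsonlite
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
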