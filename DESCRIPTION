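Package: prostaid
Title: Personalized Prostate-Cancer Treatment Decision-Aid Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested engine for personalized prostate-cancer shared decision
    making. Classifies NCCN risk groups from clinical profiles, estimates
    pre- to post-treatment toxicity transition matrices from paired
    patient-reported-outcome (PRO) records by frequentist counting, elicits
    preference thresholds and willingness-to-accept dollar valuations, and
    ranks eligible treatment alternatives with a linear additive expected-cost
    value function. Includes a synthetic-cohort generator with known
    ground-truth transition structure so every estimator and the full pipeline
    are testable without institutional datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
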