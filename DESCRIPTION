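Package: pavphot
Title: Fiber Photometry Analysis for Pavlovian Lever Autoshaping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing dual-channel (signal + isosbestic) fiber
    photometry recordings collected during Pavlovian lever autoshaping and
    reward-prediction-error probe sessions. Builds variable-interval trial
    schedules, scores sign- versus goal-tracking behaviour from operant event
    logs (Pavlovian conditioned approach score), performs isosbestic
    regression correction to obtain dF/F, aligns baseline z-scored traces to
    behavioural events, computes area-under-curve and binned contrasts
    (including cue-reward difference scores), and applies bootstrap-based
    transient inclusion criteria. Includes a phenotype-conditioned simulator
    of behaviour logs and two-channel photometry streams with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr,
    ggplot2,
    tidyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
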