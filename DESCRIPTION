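Package: cotside
Title: Evaluation of Bedside Neonatal Seizure Recognition Against Dual-Expert EEG Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well bedside clinical teams recognise
    neonatal electrographic seizures against a dual-expert continuous-EEG
    gold standard, in the setting of a two-arm multicentre randomised
    trial. Implements the consensus rule that confirms a seizure when two
    independent expert annotations overlap by at least 30 seconds,
    hour-binned seizure-burden summaries, neonate- and hour-level clinical
    recognition scoring (seizure record forms and antiseizure-medication
    rules, including false detections and inappropriate administrations),
    diagnostic-accuracy statistics with bias-corrected cluster-stratified
    bootstrap confidence intervals, post-hoc logistic interaction tests,
    sample-size arithmetic, and a synthetic cohort generator so the whole
    pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
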