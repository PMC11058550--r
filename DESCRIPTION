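Package: myotrain
Title: Biofeedback Training Logic and Adherence Analytics for Oral
    Myofunctional Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements the software logic of an ambulatory lip/tongue
    pressure-biofeedback device used for upper-airway muscle training in
    obstructive sleep apnea: zero and maximal-pressure calibration,
    timed tracking and breathing tasks with time-in-range success
    scoring, four pressure-driven training games as deterministic state
    machines, the full 35-minute session protocol with log archiving,
    a synthetic participant/cohort simulator (learning curves, thermal
    baseline drift, imperfect adherence), and the adherence/efficacy
    analytics used in clinical evaluation (compliance, success-rate
    summaries with 96% dispersion bands, Spearman correlation with
    exact permutation inference, paired sign-flip tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
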