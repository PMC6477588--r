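Package: pulmopk
Title: Noncompartmental Pharmacokinetics of Inhaled Drug Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the computational chain of rodent inhalation
    pharmacokinetic studies: exposure-atmosphere characterization from
    filter samples, cascade-impactor reduction to mass median aerodynamic
    diameter (MMAD) and geometric standard deviation (GSD) by log-probit
    regression, inhaled deposited-dose calculation with an allometric
    respiratory minute volume, below-quantification-limit (BQL) aware
    group concentration-time profiles, and noncompartmental analysis
    (Cmax, terminal half-life with best-fit lambda-z window selection,
    linear-trapezoidal AUC to the last quantifiable time, dose-normalized
    AUC). Ships the transcribed concentration tables of a published
    inhaled submicron-particle paclitaxel study as fixtures, a
    reproduction harness checking the computed pharmacokinetic summary
    against the printed values, and a synthetic-study simulator with
    known ground truth for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
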