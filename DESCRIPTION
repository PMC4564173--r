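Package: gpias
Title: Startle-Reflex Analysis of Gap Detection and Frequency
    Discrimination in Rodent Tinnitus Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing acoustic-startle-reflex (ASR) behavioural
    assays used in rodent models of tone-induced tinnitus: gap-prepulse
    inhibition of the acoustic startle (GPIAS) with a movement-artifact
    exclusion rule and Tinnitus(+)/Tinnitus(-) classification,
    prepulse-inhibition (PPI) based frequency discrimination with
    generalized-logistic psychometric fitting and threshold extraction,
    parametric-bootstrap threshold comparisons, and a repeated-measures
    ANOVA battery with Mauchly sphericity testing and Greenhouse-Geisser
    correction.  A synthetic cohort simulator generates trial schedules,
    raw force traces and per-trial startle amplitudes with configurable
    tinnitus effects so the full pipeline runs without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl
Config/testthat/edition: 3
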