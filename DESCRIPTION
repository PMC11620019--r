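Package: cypddi
Title: Screening Cytochrome P450-Mediated Drug Interactions in Hospital Prescription Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects potential cytochrome P450 (CYP450)-mediated drug-drug and
    drug-genotype interactions in electronic health record event streams. Loads
    and validates a substrate/inhibitor/inducer interaction knowledge base keyed
    by 13-digit dispensing (UCD) codes, filters it to an institutional formulary,
    renders boolean co-prescription queries, detects same-day co-occurrences per
    patient, summarises affected patients, hospitalization days and
    prescriptions per interaction rule, and computes dashboard panels (temporal
    trend, demographics, medical-unit breakdown, therapeutic drug monitoring
    coverage, dosage status). Includes a seeded synthetic EHR generator with
    plantable ground-truth interactions so the whole pipeline is testable
    without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
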