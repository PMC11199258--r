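Package: pottelscore
Title: Rescaled Creatinine (Pottel Score) Pharmacovigilance for ELBW Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects drug-associated nephrotoxicity in extremely low birth
    weight (ELBW) neonates by rescaling serum creatinine against postnatal-day
    specific reference medians (the Pottel score), encoding lagged and
    cumulative nephrotoxic-drug exposure (ibuprofen, amikacin, vancomycin),
    and fitting linear mixed models for day-wise and consecutive-day drug
    effects. Includes the neonatal modified KDIGO stage-1 creatinine rise rule
    as a comparator detector, tools to estimate day-specific p50 reference
    tables from drug-free observations, and a fully seeded synthetic ELBW
    cohort simulator so every stage of the pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    lme4,
    stats,
    utils,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
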