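Package: ivrtriage
Title: Decision-Tree Triage Engine and Evaluation Statistics for a
    Childhood-Illness Phone Hotline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative decision-tree engine for symptom triage of sick
    children by lay guardians over an interactive voice response (IVR)
    hotline, shipped with a default algorithm derived from the WHO/UNICEF
    Integrated Management of Childhood Illness (IMCI) guidelines reduced to
    ask-only dichotomous questions. Walks a validated question tree,
    accumulates disease assessments, and issues a single triage
    recommendation (emergency care, causal treatment within 24 h, or home
    care) by maximum severity. Includes the evaluation machinery for
    tool-versus-physician comparison: contingency tables, percent agreement,
    Cohen's kappa with a null-hypothesis standard error and Landis-Koch
    interpretation, diagnostic accuracy (sensitivity, specificity, PPV,
    NPV), triage dichotomization and under-triage rates, and exact
    reconstruction of integer 2x2 confusion tables from published rounded
    summary statistics. A seeded synthetic-cohort generator emulates a
    hospital validation study with per-question guardian misreporting and
    call dropout, supporting end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
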