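Package: opbpk
Title: Whole-Body PBPK Modeling and Validation for Fentanyl-Class Opioids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Perfusion-rate-limited whole-body physiologically based
    pharmacokinetic (PBPK) simulation of intravenous fentanyl-class opioids
    in rat and human. Provides tissue-to-blood partition coefficient (Kp)
    sets from packaged literature tables, a Rodgers-Rowland tissue
    composition predictor, and interspecies extrapolation; ODE simulation of
    plasma and 13 tissue compartments; non-compartmental analysis (AUC,
    terminal half-life, clearance, steady-state volume of distribution);
    fold-error scoring of predictions against observations; and synthetic
    study generation for end-to-end pipeline testing, including
    brain-to-plasma exposure ranking of analog panels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
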