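Package: dinadif
Title: DIF Detection in the DINA Model Under Q-Matrix Misspecification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for studying differential item functioning
    (DIF) detection in cognitive diagnostic models. Generates dichotomous
    response data from the DINA (deterministic-inputs, noisy "and"-gate)
    model with controlled DIF on slipping/guessing parameters and controlled
    Q-matrix misspecification, applies three DIF detection methods
    (Mantel-Haenszel, logistic regression, and a Wald test based on
    multiple-group marginal maximum-likelihood estimation), and aggregates
    per-item flag rates into Type I error and power summaries by item
    complexity and overall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
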