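Package: precav
Title: Pre-Formed Cavity Model for Cucurbituril Host-Guest Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts relative binding of rigid hydrocarbons and noble gases
    to cucurbituril-based cavities by treating the host cavity as a pre-formed
    cavity in a low-polarizability mimic solvent. Implements hard-sphere
    cavitation free energies (Boublik-Mansoori-Carnahan-Starling-Leland
    equation of state), solvation free-energy decomposition into cavitation
    and dispersion terms, gas-to-cavity transfer bookkeeping with standard
    state corrections, relative affinity estimation from competitive
    fast-exchange 19F NMR titrations, and regression-based cavity
    characterization including mixture-solvent optimization. Ships the
    curated guest, host and solvent datasets needed to reproduce the model's
    headline regressions, plus seeded simulators for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
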