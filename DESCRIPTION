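Package: pkdeplete
Title: One-Compartment Pharmacokinetics, Tissue Residue Depletion and
    Withdrawal-Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the one-compartment open model with first-order
    absorption (Bateman curve) to plasma concentration-time data, derives
    secondary pharmacokinetic parameters (half-lives, Tmax, Cmax, AUC,
    Vd/F, clearance) in closed form, fits log-linear first-order depletion
    to edible-tissue residue series with below-detection censoring, and
    projects one-sided normal tolerance limits on the depletion regression
    to estimate regulatory withdrawal times against maximum residue
    limits. Includes a synthetic-data generator with multiplicative
    lognormal error and LOD censoring for parameter-recovery studies, CSV
    readers/writers for censored concentration tables, and transcribed
    plasma and tissue residue fixtures from a donkey albendazole
    sulphoxide depletion study.
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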