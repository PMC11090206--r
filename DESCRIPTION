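Package: alkanammox
Title: Nitrogen and Electron Bookkeeping for Alkane-Oxidizing Anammox Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying syntrophic nitrogen cycling in anaerobic
    bioreactors that couple nitrate-dependent oxidation of short-chain gaseous
    alkanes (propane, butane) to anaerobic ammonium oxidation (anammox).
    Provides stoichiometric reaction bookkeeping (element, charge, electron and
    Gibbs free energy balances over a bundled reaction registry), linear-
    regression rate estimation from batch-cycle concentration time series,
    nitrogen and electron balance closure, partitioning of nitrate reduction
    between anammox-coupled nitrite consumption and denitrification, a 15N
    isotope-pairing forward model and least-squares inversion for 29N2/30N2
    isotopologue production, diagnostics for dissimilatory nitrate reduction to
    ammonium (DNRA) triggering, and a seeded bioreactor simulator for end-to-end
    validation of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
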