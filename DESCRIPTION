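Package: qsense
Title: Polarized-Light Monte Carlo and Q-Sensing of Turbid Slabs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Meridian-plane polarized-light Monte Carlo simulation of photon
    transport in polydisperse turbid slabs (Intralipid-like tissue phantoms),
    with exact Mie scattering matrices per particle size, Stokes-vector
    bookkeeping, and per-event particle-size resampling. Computes the
    Q-sensing reflectance observables (co- and cross-polarized intensities,
    Q and the normalized Q'), runs thickness and reduced-scattering sweeps,
    and inverts a simulated calibration curve to extract the reduced
    scattering coefficient from a converged Q' reading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
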