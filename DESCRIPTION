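Package: epicmc
Title: Canonical Microcircuit Modelling of NMDAR-Antibody Epileptogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multiscale analysis linking single-cell synaptic changes to
    epileptic field-potential dynamics. Provides synthetic generators for
    patch-clamp and field recordings with known ground truth, operational
    electrophysiology metrics (threshold event detection, interevent
    intervals, coastline, band power, segment classification, synaptic
    feature extraction), a four-population canonical microcircuit neural
    mass model with analytic spectral prediction and a stochastic
    time-domain oracle, variational-Laplace inversion of power spectra
    with free-energy model comparison over a 22-model space of
    microscale-informed priors, and a two-dimensional epileptogenicity by
    ictogenicity parameter-space simulation with spectral classification
    and sensitivity mapping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
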