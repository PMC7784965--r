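Package: sulfmat
Title: Microsensor Rate Inversion and Isotope-Label Budgets for Sulfidic
    Cyanobacterial Mats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of layered sulfidic
    microbial mats probed with microsensors and 13C stable-isotope
    labelling. Converts measured H2S and pH depth profiles into total
    sulfide, inverts steady-state concentration profiles into diffusive
    fluxes (Fick's first law) and piecewise-constant volumetric net rates
    (Fick's second law), extracts gross oxygenic and anoxygenic
    photosynthesis rates from light-dark shift transients, translates the
    rates into predicted CO2-fixation budgets through a two-end-member
    sulfide-oxidation stoichiometry, and computes bulk-mat, DOC and
    fatty-acid 13C label statistics. A 1D reaction-diffusion forward model
    generates synthetic mats (steady state, light-dark transients, diel
    label trajectories) for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
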