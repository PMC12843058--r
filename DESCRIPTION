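Package: spionics
Title: Magnetic Nanoparticles as Joint MRI Contrast Agents and Hyperthermia Heat Sources
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Physical modelling and data-analysis toolkit for assessing whether a
    single superparamagnetic iron oxide nanoparticle formulation can serve
    simultaneously as an MRI contrast agent and as a magnetic-hyperthermia heat
    source. Implements Neel/Brownian relaxation times, Langevin magnetization,
    Debye complex susceptibility and linear-response heating power; outer-sphere
    r1/r2 relaxivity theory with Freed spectral densities; calorimetric specific
    absorption rate (SAR) estimation from heating curves; a watershed-based
    electron-microscopy morphometry pipeline for core-diameter distributions;
    seeded synthetic-data generators for every measured input; and a
    cross-modality correlation and optimum-diameter overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
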