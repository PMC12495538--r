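Package: skinwave
Title: Millimeter-Wave Reflection and Absorption Modeling of Human Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Dispersive dielectric modeling of human skin for millimeter-wave
    dosimetry. Implements Cole-Cole/Debye permittivity models, analytic
    plane-wave reflection of stratified lossy media, a mode-matching forward
    model for open-ended rectangular waveguide probes with infinite flange
    against layered dielectrics, constrained least-squares extraction of
    layer parameters from reflection spectra, the dB-domain statistical
    pipeline used to derive population-coverage skin models, and a seeded
    synthetic cohort generator that emulates volunteer reflection
    measurements with thin and thick stratum corneum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
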