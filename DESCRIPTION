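Package: ionphantom
Title: Monte Carlo Helium-Ion Transport and Radiation Damage in Layered
    Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates therapeutic helium-4 ion beams in plane-parallel
    mandible phantoms built from real tissues or polymeric biomaterials.
    Provides Bethe electronic stopping with Bragg additivity, ZBL nuclear
    stopping, condensed-history Monte Carlo transport with Bohr energy
    straggling and Highland multiple scattering, Kinchin-Pease and NRT
    displacement-damage models with per-element recoil tallies, and
    Bragg-curve, range-straggle and cross-phantom comparison analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
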