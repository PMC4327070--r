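Package: wgmsense
Title: Analysis of Whispering-Gallery-Mode Microsphere Biosensor Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis chain for fluorescence-based
    whispering-gallery-mode (WGM) microsphere biosensors: resonance peak
    detection and Gaussian fitting with Q factors, resonator radius from the
    free spectral range, resonance-shift inversion to deposited-layer
    thickness and adsorbed protein surface mass density via the
    Clausius-Mossotti polarizability, lasing-threshold estimation from
    two-regime pump sweeps, binding-kinetics saturation metrics and
    limit-of-detection decisions, and electromagnetic (Mie characteristic
    equation) bulk refractive-index sensitivity.  Includes a seeded forward
    simulator of dye-doped microsphere emission spectra, pump sweeps,
    polyelectrolyte deposition series and binding series so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
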