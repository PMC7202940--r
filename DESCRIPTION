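Package: phasor3d
Title: Phasor-Based 3D Holographic Tracking of Microbeads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nanometric three-dimensional localization of micron-sized beads
    from in-line holographic wide-field images, as used in magnetic tweezers
    and other single-molecule force spectroscopy instruments. Provides a
    Lorenz-Mie scattering simulator for bead diffraction patterns, the 3D
    phasor tracking algorithm (band-passed FFT cross correlation with
    computer-generated single-frequency reference images; lateral position
    from the correlation amplitude peak, height from the phase with
    multi-frequency two-pi disambiguation), a radial-profile look-up-table
    baseline tracker, an image-aberration robustness benchmark, power
    spectral density accuracy metrics with common-mode drift removal, and a
    worm-like-chain probability landscape for quantifying discrete
    DNA-unwrapping steps in force-extension curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
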