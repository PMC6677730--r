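Package: holokit
Title: Lens-Less Digital Inline Holographic Microscopy Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and resolution analysis for
    lens-less digital inline holographic microscopy (DIHM). Provides
    closed-form optical design calculators (numerical-aperture and
    pixel-limited lateral resolution, optimal object distance, axial
    resolution, coherence length, Gaussian beam geometry, USAF-1951
    target arithmetic), an angular-spectrum scalar diffraction engine
    with background subtraction, refocusing, z-stacks and autofocus, a
    synthetic hologram generator for micro-spheres, phase objects and
    bar targets with a brute-force Fresnel-Kirchhoff reference
    integrator and partial-coherence averaging, and quantitative
    bar-target contrast and resolution analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
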