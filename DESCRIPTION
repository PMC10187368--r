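Package: speckletrack
Title: Wave-Optics Simulation and Sub-Pixel Tracking of X-Ray Near-Field Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-shot speckle-based x-ray phase-contrast imaging
    (XPCI). Simulates near-field speckle formation from a stacked sandpaper
    diffuser in a divergent-beam geometry via the angular spectrum method and
    the projection approximation; generates sub-pixel piecewise-smooth
    deformation datasets with attenuation and Poisson noise; tracks speckle
    displacements with windowed zero-normalized cross-correlation (ZNCC),
    unified modulated pattern analysis (UMPA), and a full-resolution
    convolutional network trained with a multiscale endpoint-error loss; and
    evaluates accuracy, spatial resolution, noise robustness and timing,
    including a sine-wave refraction phantom validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
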