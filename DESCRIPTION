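Package: fgsqc
Title: Standardized Characterization of Fluorescence-Guided Surgery Imaging Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nine-test characterization pipeline for open-field
    fluorescence-guided surgery (FGS) imaging systems: excitation-band peak
    and FWHM extraction, USAF-1951 contrast transfer function (CTF) and
    sharpness curves, depth-of-field curves, field-of-view illumination
    uniformity, dot-grid radial distortion, well-plate concentration
    sensitivity and linearity, imaging depth, and signal-to-background
    ratio in dB. Includes a synthetic phantom generator (resolution
    targets, homogeneous slabs, dot grids, concentration and depth well
    plates, excitation spectra) with a parametric camera model (defocus
    blur, vignetting, Brown radial distortion, Poisson-Gaussian noise,
    bit-depth quantization) and recorded ground truth, so every metric is
    testable without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
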