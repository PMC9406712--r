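Package: flowtomo
Title: In-Flow Digital Holographic Tomography of Rolling Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for holographic flow cyto-tomography: off-axis
    hologram demodulation, angular-spectrum refocusing with Tamura-coefficient
    autofocus, phase unwrapping and windowed-Fourier denoising, recovery of the
    rolling angles of cells translating along a 45-degree tilted microfluidic
    channel, and sparse-view refractive-index tomography by filtered back
    projection and high-order total-variation (polynomial annihilation)
    regularization with a split-Bregman solver. Includes a seeded numerical
    phantom generator and forward optical simulator, a phantom SSIM benchmark of
    the reconstruction solvers, and single-cell morphometrics (average refractive
    index, biovolume, equivalent diameter, dry mass).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
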