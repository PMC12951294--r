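Package: patrestore
Title: Photoacoustic Tomography Simulation, Filtered Back-Projection, and
    Diffusion-Based Restoration of Sparse- and Limited-View Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying image restoration in circular-array
    photoacoustic tomography (PAT). The package simulates signal acquisition
    by a ring of ultrasound detectors from two-dimensional initial-pressure
    phantoms, produces sparse-view and limited-view sinograms, reconstructs
    images by Butterworth-filtered back-projection, and restores degraded
    reconstructions with a mean-reverting stochastic-differential-equation
    diffusion model whose noise-estimation network is a time-conditioned
    transformer built from channel-transposed attention and gated
    convolutional feed-forward blocks. Includes seeded phantom generators,
    image-quality metrics (PSNR, RMSE, SSIM, line profiles), training and
    restoration drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
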