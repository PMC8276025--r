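Package: tcsem
Title: Temporal Compressive Sensing and Recurrent Reconstruction for
    Electron Microscopy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoder and learned decoder for snapshot temporal compressive
    sensing of electron-microscopy video. B consecutive frames are modulated
    by pre-determined binary masks and summed into a single coded measurement;
    a convolutional network with forward and backward recurrent refinement
    reconstructs the B frames from that measurement. Includes a synthetic
    in-situ TEM scene generator (drifting lattice fringes, moving fibers,
    Poisson-Gaussian detector noise), supervised training of the decoder,
    PSNR/SSIM evaluation against rate-matched JPEG and naive baselines, an
    FFT peak-retention diagnostic, and multipage TIFF / MRC stack I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jpeg,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
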