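Package: fibertwin
Title: Digital Twin of Multimode-Fiber Temporal Single-Pixel Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an all-fiber high-speed imaging system that encodes 2D
    images into 1D temporal pulse waveforms through intermodal dispersion in a
    long step-index multimode fiber, and decodes them with learned and linear
    inverse models. Includes a weakly-guiding LP-mode solver with per-mode
    group delays, a forward encoder (modal coupling, delayed sub-pulses,
    detector response, sampling, noise), seeded synthetic pattern generators
    (glyphs, random strokes, resolution bars, grayscale blobs), fully
    connected, convolutional and ridge-pseudoinverse decoders trained on
    simulated waveform/image pairs, image-fidelity metrics (pixelwise Pearson
    correlation and SSIM), waveform classification, and scripted studies of
    fiber-length ablation, frame rate, perturbation robustness and spatial
    resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
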