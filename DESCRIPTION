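Package: ecgspectro
Title: ECG Denoising, Frequency-Domain Reduction, Spectrogram Imaging and
    Compact CNN Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pipeline for binary classification of single-lead ECG records
    via spectrogram images. Implements single-level biorthogonal wavelet
    denoising with a universal threshold, Fourier-domain frequency-bin
    deletion for data reduction, short-time Fourier transform spectrogram
    rendering to 64x64 grayscale images, class balancing by image
    augmentation, and a compact four-block convolutional neural network
    trained with Adam on binary cross-entropy. Includes a seeded synthetic
    two-class ECG generator and WFDB format-16 record input/output so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
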