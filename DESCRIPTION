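Package: eegtfr
Title: Time-Frequency Imaging and Therapy-Response Classification for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting depression therapy response from resting-state
    multichannel EEG. Implements preprocessing (zero-phase band-pass and notch
    filtering, common average referencing, epoch segmentation, multiscale PCA
    wavelet denoising), a from-scratch variational mode decomposition (VMD)
    solver, analytic Morlet continuous-wavelet scalograms, aggregate VMD
    spectrograms with pixel-level image fusion, a compact neural-network model
    zoo with a hybrid convolutional/transformer classifier, and a dual
    image-level / subject-independent cross-validation protocol with majority
    voting, confidence intervals and exact Wilcoxon signed-rank model
    comparison. A synthetic EEG cohort generator with known ground truth makes
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
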