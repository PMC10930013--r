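Package: CACdenoise
Title: Quantum-Noise Removal for Thin-Slice Coronary Artery Calcium CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residual-learning removal of quantum noise from thin-slice
    (0.5/1.0/1.5 mm) coronary artery calcium (CAC) CT reconstructions. A
    dense-connectivity convolutional network is trained to map pseudo noise
    maps (thin image minus its 2x2-block-downsampled, bicubically upsampled
    self) to real noise maps (thin image minus the co-located 3-mm image);
    denoising subtracts the predicted noise map from the thin image. Includes
    a calibrated simulator of CIRS-style electron density phantoms and
    QRM-style anthropomorphic thorax phantoms that generates paired thin and
    3-mm reconstructions with correlated Gaussian noise, the rod-removal
    acquisition protocol used to build training data, and an evaluation suite
    (RMSE/PSNR, ROI statistics with Welch t-tests, calcification segmentation
    at the 130 HU threshold, Dice coefficients, and Agatston weighting-bin
    pixel counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'evaluation.R'
    'io.R'
    'model.R'
    'noise_maps.R'
    'phantoms.R'
    'pipeline.R'
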