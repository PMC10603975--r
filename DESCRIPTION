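Package: munetseg
Title: Light U-Net Architectures for Brain Organoid Bright-Field Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of brain organoids in bright-field microscopy
    images from very small datasets. Implements Mu-Net, a lightened U-Net
    encoder-decoder, together with U-Net and UNet-Mini comparators and an
    18-configuration ablation grid built from six toggleable design
    components; a self-contained CPU training engine (Adam, binary
    cross-entropy, early stopping on loss plateau); the leave-one-out
    training protocol with per-fold augmentation groups (classic
    geometric/whitening transforms and noise-injection strategies); five
    classical segmentation baselines (fixed/Otsu thresholding, region
    growing, PSO-initialised k-means, Chan-Vese active contour, marker
    watershed); confusion-matrix metrics (Dice, accuracy, sensitivity,
    specificity, precision, F1) with overlay rendering and tabular reports;
    and a synthetic organoid phantom generator with paired ground-truth
    masks so every stage is testable without access to restricted imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'architecture.R'
    'augment.R'
    'classical.R'
    'config.R'
    'engine.R'
    'evaluation.R'
    'imaging.R'
    'munetseg-package.R'
    'phantom.R'
    'training.R'
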