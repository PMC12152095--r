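Package: aphidSID
Title: Hyperspectral Detection and Quantification of Sub-Leaf Aphid
    Infestation by Spectral Information Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of visible/near-infrared (VNIR)
    hyperspectral leaf imagery for detecting and quantifying black bean
    aphid (Aphis fabae) colonies hidden beneath faba bean (Vicia faba)
    leaves. Provides reflectance calibration, chemometric pre-treatments
    (standard normal variate, log(1/R), Savitzky-Golay derivatives),
    SVM-based plant/background segmentation with morphological mask
    cleaning, N-FINDR endmember extraction with fully constrained linear
    unmixing, per-pixel Spectral Information Divergence (SID) abundance
    mapping in configurable wavelength windows, random-forest wavelength
    selection, multi-classifier infestation detection with a stratified
    repeated cross-validation protocol, and partial least squares (PLS)
    regression of aphid counts with severity banding. A synthetic scene
    generator with pixel-level ground truth supports testing and
    calibration without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    class,
    nnet,
    randomForest,
    signal,
    png,
    jsonlite,
    yaml,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
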