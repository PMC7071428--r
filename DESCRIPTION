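Package: depthPA
Title: Physical Activity Intensity Estimation from 3D (Infrared + Depth) Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts paired infrared/depth video of indoor play into
    triaxial physical-activity acceleration vector-magnitude signals and
    classifies 5-second epochs into sedentary, light, and moderate-vigorous
    intensity against direct-observation ground truth. Implements
    frame-differencing segmentation with a morphological clean-up chain,
    multi-object blob tracking with Kalman smoothing, Fourier-transform
    velocity estimation per movement plane, a metric calibration mapping
    pixel sizes to metres as a function of depth, CARS-style second-by-second
    observation reintegration, single-feature CART/multiclass-CART intensity
    classifiers with ROC evaluation, and nonparametric TOST equivalence
    testing of observed versus estimated time-use. Includes a synthetic
    frame generator that renders moving-blob infrared/depth sequences with
    known trajectories for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    rpart,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification
RoxygenNote: 7.3.3
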