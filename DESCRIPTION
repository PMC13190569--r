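Package: edfm
Title: Closed-Loop Morphology-Physiology Simulation of Maize Organ Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A functional-structural simulator of maize organ growth that
    couples gated-attention fusion of environmental, image and point-cloud
    features with a daily morphology-physiology feedback loop: thermal-time
    phenology, sink-strength assimilate allocation, water-stress-modulated
    logistic organ expansion on NURBS surfaces, and ray-traced canopy light
    capture feeding back on photosynthetic capacity. Includes synthetic
    weather/point-cloud/trait generators, the preprocessing pipeline
    (z-score normalization, statistical outlier removal, voxel
    downsampling, image standardization, plant-level splits), one-at-a-time
    sensitivity analysis, and evaluation utilities (RMSE, R-squared, NRMSE,
    benchmark comparison, logistic growth-curve fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
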