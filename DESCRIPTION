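Package: thermowave
Title: Physics-Assisted Deep-Learning Microwave Thermometry for Hyperthermia Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-frequency microwave scattering from a synthetic 2D
    neck phantom at hyperthermia treatment temperatures, reconstructs the
    differential dielectric contrast in the tumor and spinal-cord regions of
    interest with a distorted-wave Born approximation inverted by truncated
    singular value decomposition, and classifies each region's thermal status
    with compact convolutional neural networks. Includes temperature-dependent
    Cole-Cole tissue dielectrics, a method-of-moments forward solver with an
    analytic cylinder-series oracle, dataset generation with tissue
    randomization and measurement noise, K-fold training, and Dice and Matthews
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
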