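Package: pancortex
Title: Pan-Cortical Mesoscale Calcium-Imaging Registration and
    Neurobehavioral Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mesoscale two-photon calcium imaging of
    mouse cortex: widefield multimodal sensory mapping, two-step landmark
    registration assigning every imaged neuron to an Allen CCF cortical
    area, neuropil-subtracted rolling-percentile dF/F extraction on a
    common 10 Hz grid, and neurobehavioral alignment statistics relating
    single-neuron activity to arousal and movement primitives (walk speed,
    whisker motion energy, pupil diameter). Includes raster sorting by
    principal-component loading and by asymmetric cross-correlation
    similarity, superneuron averaging, per-area correlation statistics,
    group density maps, and a fully ground-truthed synthetic session
    generator so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
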