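Package: dtscnn
Title: Dual-Threshold Spiking Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training and complexity profiling of spiking
    convolutional neural networks (SCNNs) with dual-threshold leaky
    integrate-and-fire (DT-LIF) neurons. A dual-threshold convolutional
    (DTC) layer derives two binary spiking feature maps from a single
    membrane-potential map, halving convolutional weights, membrane
    storage and convolution operations relative to a conventional SCNN
    with the same feature-map count. Networks are trained with a variant
    of surrogate-gradient spatio-temporal backpropagation (STBP) that
    routes errors through both threshold pathways and learns the firing
    thresholds, using a two-stage strategy (pre-train at five timesteps,
    re-train at one) so that inference needs a single timestep. Includes
    an operation/weight/membrane-storage profiler (ACC/MAC accounting),
    spiking-feature-map similarity analysis, a synthetic image-set
    generator, IDX-format image I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
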