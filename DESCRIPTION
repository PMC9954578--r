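Package: stipnet
Title: Spike-Train Inner-Product Learning for Deep Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based supervised learning for deep spiking neural networks.
    Spike trains are embedded in a reproducing-kernel Hilbert space through
    positive-definite spike-time kernels (Gaussian, Laplacian, inverse
    multiquadratic, alpha), and network error is the squared RKHS distance
    between actual and desired output trains, computed in closed form as a
    double sum over spike-time pairs (the spike-train inner product). Weight
    updates are derived from this error under three feedback pathways: exact
    error backpropagation, feedback alignment through fixed random layer-wise
    matrices, and broadcast alignment through fixed random per-layer broadcast
    matrices. Includes a clock-driven leaky integrate-and-fire simulator,
    Poisson rate encoders and nearest-template decoders, a synthetic
    classification-task generator, an IDX image reader, and a command-line
    interface for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
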