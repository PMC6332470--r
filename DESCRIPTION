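Package: adsnn
Title: Adaptive Spiking Neural Networks with Spike-Based Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of adaptive spiking neurons (ASNs) whose dynamic
    threshold implements firing-rate-limiting spike-frequency adaptation,
    together with the analytically derived transfer function that maps an
    activation to the mean postsynaptic contribution. Analog networks trained
    with this transfer function can be converted into spiking networks that
    communicate with binary spikes; the package provides the conversion rules
    (batch-normalization folding, pooling merge, smoothed readout), a
    time-stepped network simulator with evaluation metrics (firing rate,
    matching time, spike and synaptic-operation counts), and an
    uncertainty-gated arousal mechanism that trades firing rate against
    neural coding precision per input. Seeded synthetic data generators and a
    small dense-network trainer make the whole pipeline reproducible at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
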