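Package: wtastdp
Title: Unsupervised Convolutional Feature Learning with Winner-Takes-All
    Binary STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains convolutional feature banks without labels using a
    spike-timing-dependent plasticity (STDP) rule adapted to static images.
    Leaky integrate-and-fire neurons driven by constant input are equivalent
    to rectified-linear units, so a whole spiking network pass reduces to a
    single feed-forward convolution whose activation magnitudes encode first
    spike order. A three-stage winner-takes-all competition (neighbourhood
    max-pooling, channel competition, spatial competition) selects at most
    one input patch per output channel and image; selected patches drive a
    binary Hebbian update with an adaptive LTP/LTD threshold, aggregated over
    mini-batches into a single +/- lambda step, followed by heterosynaptic
    weight normalization and clipping. Includes a seeded synthetic-data
    generator with planted repeating patterns, ON/OFF difference-of-Gaussians
    encoding, IDX file input/output, architecture presets, and evaluation
    utilities (pattern-recovery scoring, weight statistics, linear readout).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
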