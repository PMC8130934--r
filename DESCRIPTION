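Package: hippophen
Title: In Vivo Oscillatory Phenotyping of Hippocampal Neuron Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects theta cycles, sharp-wave ripples and dentate spikes in
    multichannel hippocampal LFP recordings; computes per-cell oscillatory
    phenotypes (preferred theta phase, mean vector length, event-modulation
    ratios, bursting index, membrane biophysics); normalizes
    literature-reported firing phases from any hippocampal or entorhinal
    layer to the CA1 stratum pyramidale reference; aggregates evidence into
    a neuron-type knowledge base; classifies extracellular units against
    knowledge-base clusters; and screens pairwise associations between
    neuron-type properties with Barnard's exact unconditional test and
    Spearman rank correlation. Includes a synthetic-data generator
    (layered theta, ripple bursts, dentate spikes, von Mises phase-locked
    spike trains, current-step membrane traces) so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
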