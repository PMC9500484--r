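Package: ca1som
Title: Hippocampus-Inspired Continual Learning with Novelty-Gated Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulator of the hippocampal CA1 region as a
    self-organizing competitive map with biologically motivated safeguards
    against catastrophic interference. Pyramidal cells and interneurons lie
    on toroidal 2D grids with distance-dependent stochastic connectivity
    (narrow Gaussian excitation, Mexican-hat lateral inhibition). A
    Subiculum-Accumbens/Pallidum-VTA novelty circuit gates an Oja-like
    Hebbian rule on the input synapses through a binary phasic dopamine
    signal, and a homeostatic rule strengthens lateral inhibition onto
    learning neurons. Includes synthetic stimulus generators (digit-like
    sets and textured corridors), an MNIST IDX reader, the
    catastrophic-forgetting and lifelong two-corridor evaluation protocols
    with lesion conditions, and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    data.table,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
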