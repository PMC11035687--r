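Package: ccnnsat
Title: Continuous Coupled Neural Network Models of Semantic Satiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates an artificial ventral visual pathway built from a
    continuous coupled neural network (CCNN) lattice standing in for primary
    visual cortex and a dense readout standing in for inferior temporal
    cortex, and uses it to model semantic satiation: the transient loss of a
    stimulus's meaning under repeated presentation. Provides the PCNN and
    CCNN lattice update rules, training of the coupling kernels and readout
    by backpropagation through time, repeated-stimulus and prime/target
    experiment protocols, an N400-style population statistic, structural
    similarity (SSIM) between image categories, inter-/intra-class semantic
    distances, IDX dataset input/output, a synthetic stroke-glyph dataset
    generator, state visualization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
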