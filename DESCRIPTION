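Package: dendnorm
Title: Dendritic Normalisation for Sparsely Connected Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements dendritic (L0) weight normalisation and its Lp
    generalisations for sparsely connected feedforward and recurrent
    artificial neural networks trained with stochastic gradient descent and
    backpropagation through time under sparse evolutionary rewiring (SET).
    Provides the passive-cable theory that grounds the normalisation
    (transfer resistances, distributed-synapse voltage moments, transient
    responses, and a compartmental oracle), exact cost-gradient transforms
    for constant and per-neuron excitability, synthetic task generators
    (binary addition sequences, parametrised image classes, letter-sequence
    stimuli), connectivity analytics (degree distributions, efferent maps,
    average shortest path lengths), and a self-organising recurrent network
    of spiking neurons whose equivalent-cylinder dendrite length tracks
    afferent connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
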