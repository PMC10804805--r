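Package: snnsim
Title: Clock-Driven Simulation and Training of Compact-Model Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact-model spiking neural network simulator aimed at
    prototyping hardware neuromorphic systems. Networks are built from
    vectorized "groups" of identically-modeled components (leaky
    integrate-and-fire, leaky-integrator and Izhikevich neurons; first- and
    second-order leaky synapses with delays and refractoriness), executed by
    a fixed-time-step clock-driven engine whose group evaluation order is
    derived automatically from a delay-substituted directed adjacency matrix,
    so feedforward and recurrent topologies share one code path. Includes
    state monitoring, surrogate-gradient backpropagation-through-time
    training of synaptic weights with a max-membrane-potential readout,
    spike encoders (rate, delta, spline upscaling), synthetic dataset
    generators, a configurable liquid-state-machine builder, and
    post-training hardware non-ideality analysis (stochastic weight
    quantization onto equidistant levels, power-law conductance drift).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
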