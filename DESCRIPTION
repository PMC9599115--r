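Package: spinecap
Title: Spine Calcium Dynamics and Calcium-Based Synaptic Plasticity in a
    Reduced Striatal Projection Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates calcium-based synaptic plasticity under in vivo-like
    cortical input. Provides generators for correlated excitatory spike
    trains with controlled trial-to-trial variability (spike-time jitter,
    spike moving between trains, interspike-interval shuffling) and Poisson
    inhibitory trains; a reduced multicompartment spiny projection neuron
    with explicit dendritic spines, dual-exponential AMPA/NMDA/GABA-A
    synapses and a minimal spiking soma; a mechanistic spine and dendrite
    calcium model with mobile and immobile buffers, Michaelis-Menten
    membrane pumps and one-dimensional diffusion; a dual amplitude/duration
    calcium-threshold weight-update rule; and analysis tools including
    weight-change triggered averages, time-sample feature construction,
    random-forest prediction of weight change and pre/post spike-interval
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
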