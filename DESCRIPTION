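Package: spikelearn
Title: Teacher-Student Learning Curves for Asynchronous Spiking Perceptrons
Version: 0.1.0
Authors@R:
    person("spikelearn", "developers", email = "spikelearn@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of supervised learning in feedforward
    networks of leaky integrate-and-fire neurons driven by asynchronous
    inputs. Implements teacher-student perceptrons with spike-timing-dependent
    multiplicative adaptation of synaptic weights or of dendritic strengths
    bounded between reflecting limits, perceptron-style learning steps derived
    from an output-mismatch cost, a one-hidden-layer extension, and the
    machinery to measure generalization-error learning curves, parameter
    overlaps, frozen-dendrite fractions and power-law decay exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
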