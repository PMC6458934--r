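Package: gesnn
Title: Grammatical Evolution of Partially Connected Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs partially connected three-layer feedforward spiking
    neural networks for supervised classification by grammatical evolution.
    A context-free grammar in Backus-Naur form generates network words that
    fix the topology, synaptic weights and delays in a single search (no
    separate weight training); candidate genotypes are optimized with a
    genetic algorithm over bitstrings or differential evolution over real
    vectors. Neurons follow the Spike Response Model, scalar features are
    mapped to input spike times by a linear one-dimensional temporal
    encoding, and classes are read out from the output neuron's
    time-to-first-spike against per-class target firing times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
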