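Package: triadnet
Title: Local Synaptic Learning Rules in Three-Layer Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and compares biologically plausible local synaptic
    learning rules -- backpropagation, feedback alignment and its
    excitatory/Bernoulli/normal feedback variants, the extreme learning
    machine, and weight perturbation -- on the k-dXOR reward-prediction
    task in a three-layer rate network.  Includes a family of perturbed
    activation-derivative surrogates for robustness studies,
    seed-replicated learning-curve experiments, epoch-to-threshold
    analysis, and tidy CSV export of all results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
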