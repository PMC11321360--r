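Package: selhmm
Title: Selection Coefficient Inference from Allele-Frequency Hidden Markov Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Full-likelihood inference of natural selection from ancient
    genotype time series, gene trees, and gene trees with ancient leaves.
    The historic frequency of a derived allele is modelled as the hidden
    state of a hidden Markov model with Gaussian drift-plus-selection
    transitions on an arcsine-spaced frequency grid; emissions come from
    Hardy-Weinberg genotype likelihoods, structured-coalescent waiting
    times of labelled gene trees, and ancient leaf sampling events.
    Supports epoch-wise selection coefficients with likelihood-ratio
    tests and AIC model choice, importance sampling over sampled marginal
    gene trees, posterior reconstruction of historic allele-frequency
    trajectories that integrates over selection-coefficient uncertainty,
    and matched simulators (including a rejection-sampling posterior
    oracle) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
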