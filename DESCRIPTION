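Package: tuningscape
Title: Evolutionary Analysis of Olfactory Receptor Tuning from
    Single-Sensillum Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies odor-evoked responses of insect olfactory sensory
    neurons from extracellular spike trains (windowed spike counts, solvent
    correction, per-sensillum max-normalization and z-scoring), summarizes
    tuning profiles by principal component analysis with the first component
    as a scalar tuning phenotype, reconstructs ancestral tuning states on a
    species phylogeny by small parsimony, and maps the evolutionary landscape
    between two receptor alleles over the 2^n genotype hypercube, classifying
    stepwise mutational paths and detecting epistasis between substitutions
    with a bootstrap test of additivity. Includes seeded generators for
    Poisson spike trains and genotype response panels with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
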