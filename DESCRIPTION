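Package: loxevo
Title: Evolutionary Analysis of Lysyl Oxidase Domain Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for tracing the evolution of lysyl oxidase
    (LOX) proteins across the tree of life: profile hidden Markov model
    scanning of proteomes for LOX and accessory domains, annotation of
    signal peptides, transmembrane helices, proline-rich and propeptide
    regions into canonical domain architectures, classification of
    catalytic competence from the copper-binding histidine core and the
    lysyl tyrosyl quinone (LTQ) lysine/tyrosine pair, progressive multiple
    alignment, maximum-likelihood phylogenetics with model selection and
    bootstrap support, bipartition-based convergence diagnostics for tree
    samples, reciprocal-hit similarity networks for horizontal gene
    transfer assessment, and Dollo parsimony reconstruction of family and
    domain gains and losses on a species tree. Includes a synthetic
    proteome generator that plants duplications, losses, transfers and
    catalytic knockouts with a machine-readable ground-truth log, so the
    whole pipeline can be exercised end to end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
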