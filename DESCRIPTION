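Package: somamap
Title: Somatotopic Connectome Analysis of Bristle Mechanosensory Neurons
Version: 0.1.0
Authors@R: person("somamap", "developers", role = c("aut", "cre"),
    email = "somamap@example.org")
Description: Tools to establish somatotopic organization in reconstructed
    sensory neuron populations: SWC skeleton reading, region pruning and
    resampling; NBLAST-style morphological similarity with Ward clustering;
    synapse-table filtering and type-level connectivity normalized by
    possible edges; cosine-similarity clustering of postsynaptic
    connectivity profiles; dominant-input partner assignment and thresholded
    type-to-partner-group graphs; midline-crossing laterality; and a seeded
    generator of ground-truthed synthetic somatotopic connectomes for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    ape,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
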