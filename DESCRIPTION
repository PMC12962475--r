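Package: songpath
Title: Path-Length Song Complexity and Operant Preference Analysis for Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the "path length" holistic measure of birdsong complexity
    and for the operant two-choice preference experiments built around it.
    Synthesizes parametric syllables and five-syllable motifs, converts syllable
    waveforms to fixed-size colormapped spectrogram pixel vectors, embeds and
    clusters syllables in two dimensions, and computes shortest Hamiltonian path
    lengths over cluster centroids under several distance metrics. Also simulates
    and analyzes operant choice sessions with a Bayesian hierarchical logistic
    model (random bird intercepts, optional fixed effects, approximate
    leave-one-out model comparison) and provides a Gelman-Carlin style design
    analysis (power, Type S, Type M) for planned preference experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    rjags,
    coda,
    sandwich,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4,
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
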