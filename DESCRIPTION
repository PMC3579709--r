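Package: metcoher
Title: Metabolic Coherence and Expression-Constrained Flux Inconsistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of two ways of confronting transcriptome
    data with a constraint-based metabolic model: the GIMME-style linear
    programming inconsistency score, which measures how much flux must be
    routed through below-threshold ("absent") reactions to sustain a
    metabolic objective, and the purely topological metabolic coherence
    z-score, which measures how connected the above-threshold gene set is
    inside a gene network projected from the model. Includes SBML model
    input/output, gene-protein-reaction rule evaluation (AND/OR as min/max),
    growth-medium handling with random-medium sampling, decomposition of the
    inconsistency into per-reaction contributions with topological marker
    classification (bottleneck, chain disruptor, invisible path,
    input/output-layer proximity, just-below-threshold), correlation sweeps
    over threshold, objective level and media, and a seeded synthetic model
    and cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
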