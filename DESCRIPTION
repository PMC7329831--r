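Package: metadbg
Title: Desk-Scale Iterative Multi-k Metagenome Assembly, Scaffolding and
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single-process short-read metagenome assembler built around an
    iterative multi-k de Bruijn graph: Bloom-filtered exact k-mer counting
    with quality-gated extension records, adaptive-threshold contig
    traversal, graph refinement (bubble merging, hair removal, depth-based
    fork pruning), read-based local contig extension, and a contig-graph
    scaffolder driven by splint and span evidence with depth-guided fork
    resolution and read-based gap filling. Ships a ground-truthed
    paired-end metagenome read simulator (lognormal community abundances,
    replicate samples, per-read provenance) and an evaluation module
    (genome fraction, duplication ratio, chimericity entropy, cumulative
    aligned length, coassembly versus multiassembly comparisons), so that
    pooled-versus-per-sample assembly experiments can be run end-to-end on
    generated data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
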