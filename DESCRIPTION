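Package: pnpkit
Title: Proneuropeptide Discovery, Processing and Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing proneuropeptides (pNPs) from transcriptome
    assemblies: six-frame longest-ORF calling, signal-peptide gating and
    in-silico signal-peptide removal to derive a secretome, detection of mono-,
    di- and multibasic prohormone-convertase cleavage sites, liberation of
    mature peptides with C-terminal amidation and N-terminal pyroglutamate
    calls, repeat-motif scanning, position-frequency matrices for repetitive
    peptides, matching of mass-spectrometry peptide evidence, bona fide
    prohormone qualification, e-value thresholded sequence-similarity cluster
    maps with motif-based family assignment, and stage-specific expression
    profiling (rpm/RPKM normalization, minimum-expression filtering,
    Pearson-distance hierarchical clustering). Includes a synthetic precursor
    and count-matrix generator with full ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
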