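Package: tehorizon
Title: DNA Transposon Annotation, Divergence Landscapes, and Horizontal-Transfer Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the evolution of cut-and-paste DNA
    transposons (pogo/Tigger-like elements) in animal genomes.  Provides a
    synthetic-data generator (species trees, neutrally evolving host genes,
    transposon copies with terminal inverted repeats and TA target-site
    duplications, optional horizontal-transfer histories), translated
    homology mining with hit consolidation and copy-census thresholds,
    element boundary annotation (TIR/TSD/ORF) and copy classification,
    pairwise genetic distances (Kimura two-parameter and composite-likelihood
    Tamura-Nei with pairwise deletion), neighbor-joining clustering, Kimura
    divergence landscapes, and a three-filter horizontal-transfer detector
    with secondary-gene confirmation, validated against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
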