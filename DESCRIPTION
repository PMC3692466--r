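Package: mtsprofiler
Title: Physicochemical Profiling of Mitochondrial Targeting Signals and
    Their Mature Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico analysis of N-terminal mitochondrial
    matrix targeting signals (MTSs) paired with the mature sequences they
    import. Computes per-sequence physicochemical profiles (length, net
    charge at a configurable pH from a Henderson-Hasselbalch pKa model,
    isoelectric point by bisection, and nine reduced-alphabet group
    fractions), species-stratified and pooled Spearman rank-correlation
    matrices between MTS and mature-sequence properties, principal component
    analysis of standardized property tables with Kaiser retention, windowed
    N-terminal composition analyses, and secondary-structure comparisons
    between shortest- and longest-MTS groups. Includes a Gaussian-copula
    synthetic-data generator that emulates the species structure and
    composition biases of curated matrix-protein datasets so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Proteomics, SequenceMatching, StatisticalMethod
RoxygenNote: 7.3.3
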