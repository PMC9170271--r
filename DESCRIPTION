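Package: sscascade
Title: Evidential Cascade Classification for Protein Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue protein secondary structure prediction with a
    multistage combination classifier: a shared multilevel feature
    extractor (per-block linear projections, multiscale one-dimensional
    convolutions, bidirectional gated recurrent contexts and sequential
    attention) feeds an easy linear classifier and a hard multilayer
    classifier.  Residues are routed between the two by an evidential
    rule built on Dirichlet opinions and information entropy, and the
    combined training objective accumulates extra penalty on hard
    residues.  Includes readers and writers for the packed 700x57
    CullPDB-style benchmark arrays, the 50-dimensional residue feature
    encoding (one-hot, profile, physicochemical properties and a
    conservation score), a seeded synthetic-data generator with planted
    easy and hard residues, seeded training with Adam, Q3/Q8 scoring
    with confusion-matrix reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
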