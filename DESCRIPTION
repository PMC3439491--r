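Package: cargbend
Title: CArG-Box Motif Scanning and Protein-Induced DNA Bend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of MADS-domain transcription factor
    interactions with CArG-box DNA elements. Provides a degenerate-consensus
    scanner for the canonical, SRF-like (SRE), MEF2-like (N10) and
    intermediate CArG classes with a configurable atypical-base budget;
    circular-permutation analysis of electrophoretic mobility shift data
    with cosine fitting and bend-angle estimation via the relation
    muM/muE = cos(alpha/2); helical phasing analysis at the B-DNA repeat
    (10.5 bp/turn) with in-phase/out-of-phase classification;
    one-site saturation binding (Bmax, Kd) and ligase-mediated
    circularization kinetics; and seeded synthetic-data generators with
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
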