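Package: cysmotif
Title: Cysteine-Motif Screening for Antimicrobial Peptides in Plant Transcriptomes
Version: 1.0.0
Authors@R:
    person("cysmotif", "maintainers", email = "cysmotif@example.org", role = c("aut", "cre"))
Description: Screens transcriptome assemblies for antimicrobial and other
    cysteine-rich peptides. Implements a small pattern language for cysteine
    motifs (cysteine anchors separated by bounded non-cysteine gaps), six-frame
    translation and open-reading-frame extraction, a filtration cascade
    (precursor length, methionine start, a transparent signal-peptide
    heuristic), classification of candidates into plant AMP families
    (defensins, thionins, cyclotides, snakins, hevein-like peptides,
    lipid-transfer proteins) or an artificial cysteine-rich group,
    false-positive calibration on random sequences, per-family count tables,
    and alignment-based consensus/conservation reports. A seeded synthetic
    transcriptome generator with planted, ground-truthed precursors makes the
    whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
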