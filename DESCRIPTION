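Package: phosphatr
Title: Phosphatase Holoenzyme Substrate Discovery and Validation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and validates substrates of sequence-specific
    protein phosphatase 1 (PP1) holoenzymes such as Phactr1/PP1. Implements
    forward/reverse SILAC dephosphorylation scoring, rank-based annotation
    enrichment of the scores, positional amino-acid frequency contrasts and
    a flexible-spacing scanner for the S/T-x(2-3)-phi-L dephosphorylation
    motif, single-timepoint Michaelis-Menten kinetics with enzyme-unit
    calibration and pNPP normalisation, 1:1 Langmuir biolayer-interferometry
    binding fits, and TMT differential phosphoproteomics with Welch testing.
    A seeded synthetic-data module generates every input with ground-truth
    labels so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
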