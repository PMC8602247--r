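Package: phosphoDIA
Title: In Silico Spectral Libraries and Error Control for DIA Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building in silico spectral libraries for
    data-independent acquisition (DIA) phosphoproteomics. Implements a
    hybrid recurrent/self-attention neural network (trained with a small
    built-in reverse-mode autodiff engine) that predicts phosphopeptide
    MS/MS fragment-ion intensities on a masked L-by-8 b/y-ion channel
    space with H3PO4 neutral-loss handling, and indexed retention time
    (iRT) via an ensemble regressor. Around the models it provides
    tryptic in silico digestion with phosphosite-driven peptide
    enumeration, spectral-library construction (predicted, hybrid,
    focused, reverse-decoy and two-species entrapment libraries) with
    TSV serialization, evaluation metrics (Pearson correlation,
    normalized spectral angle, delta-t95), target-decoy and entrapment
    false discovery rate estimators, false localization rate, and
    two-proteome quantification statistics (measured ratios, false
    quantification rate, replicate CV). Seeded synthetic-data
    generators make the whole stack testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
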