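Package: oriseq
Title: Sequence Signatures and Positional Genomics of Yeast Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the sequence context of DNA replication
    origins (ORIs) in budding yeast. Computes compositional signals (GC
    profile, GC skew), informational statistics (Shannon entropy and k-order
    information redundancy, a lagged mutual-information measure of base
    correlation), anchored metagene profiles around ORIs, positional
    classification of ORIs relative to genes, transcription start sites and
    intergenic-region orientation, and support-vector-machine discrimination
    of ORI windows from upstream windows under stratified cross-validation.
    Includes a synthetic genome generator that plants AT-rich, motif-bearing,
    nucleosome-depleted origins so every stage can be validated against known
    ground truth without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
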