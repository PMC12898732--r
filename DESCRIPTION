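Package: barhrm
Title: Bar-HRM Species Authentication from High-Resolution Melting Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for authenticating closely related plant species by
    DNA barcoding coupled with high-resolution melting (Bar-HRM).
    Covers the full desk workflow: alignment of barcode sequences and
    discovery of species-diagnostic variants, enumeration and screening
    of candidate amplicons, nearest-neighbor thermodynamic melting
    temperature prediction with a hairpin free-energy screen,
    processing of fluorescence melting curves (derivative peaks,
    two-window normalization, difference curves, genotype calling with
    confidence), neighbor-joining phylogenetic cross-validation with
    bootstrap supports, and a seeded simulator of melt-curve cohorts
    for method development and validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
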