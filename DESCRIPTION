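Package: mamtools
Title: Multi-Attribute Method Toolkit for Antibody Quality Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-attribute method (MAM) workflow for
    monoclonal-antibody quality monitoring from peptide-map LC-MS data:
    in-silico tryptic digestion and product-quality-attribute (PQA) panel
    enumeration, extracted-ion-chromatogram peak integration and relative
    quantification, Fc glycoform profiling, untargeted new-peak detection
    against a reference run, charge-state deconvolution of reduced-subunit
    spectra for light-chain glycation, and the associated QC statistics
    (detection and quantification thresholds, tiered pass/fail criteria,
    RSD precision, Bland-Altman comparability). A seeded simulator
    generates ground-truthed DDA peptide-map runs and subunit envelopes so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    mzR,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
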