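Package: citrullinr
Title: Citrullination-Site Assignment, Motif Scanning and Differential
    Analysis for Plant Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing protein citrullination (arginine
    deimination) from tandem mass spectrometry evidence. Implements
    in-silico tryptic digestion, monoisotopic mass bookkeeping for
    modified peptides and their b/y fragment ions, tolerance-based
    peak matching against MGF spectra, localization of the +0.984 Da
    mass shift with explicit disambiguation of citrullination (R)
    from deamidation (N/Q), the isocyanic-acid (43 Da) neutral-loss
    diagnostic, sequence-context logos and PROSITE-style motif
    scanning with bounded gaps, and threshold-based categorization of
    citrullination changes across a stress time course (baseline,
    increased, decreased, de novo, lost). A seeded synthetic-data
    generator produces spectra, proteomes and quantification tables
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
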