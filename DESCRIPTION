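Package: glutenxl
Title: Identification of Transglutaminase 2-Gluten Isopeptides from Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reciprocal search pipeline for N-epsilon-(gamma-glutamyl)-lysine
    isopeptides between human tissue transglutaminase (TG2) tryptic peptides and
    wheat, rye and barley gluten peptides. Provides elemental-composition
    arithmetic with crosslink-as-modification construction (peptide minus NH3),
    in-silico multi-enzyme digestion, crosslink-aware b/y/a/internal fragment
    enumeration, spectrum search with binomial scoring and crosslink/deamidation
    site localization, replicate and negative-control confirmation rules,
    parallel reaction monitoring (PRM) isolation-list export and chromatogram
    analysis, TG2 glutamine specificity-motif classification, and a seeded
    synthetic-data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    xml2,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
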