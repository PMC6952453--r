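Package: dialib
Title: In Silico Spectral Libraries for Data-Independent Acquisition Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds instrument-specific in silico spectral libraries for
    data-independent acquisition (DIA) proteomics. Hybrid convolutional +
    bidirectional LSTM networks predict peptide MS/MS fragment-ion
    intensities (b/y ions with ammonia and water losses, charge 1+/2+),
    indexed retention time (iRT) and peptide detectability from sequence.
    Includes in silico tryptic digestion of protein FASTA databases,
    annotation of experimental DDA spectra into training targets,
    entrapment-library construction, Spectronaut-style CSV library export,
    evaluation metrics (normalized dot product, iRT statistics, entrapment
    percentage, sensitivity, CV, percent change), and seeded synthetic-data
    generators with known ground-truth rules for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    mzR,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
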