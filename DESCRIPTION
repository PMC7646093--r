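Package: dialib
Title: Construction of DIA and PRM Spectral Libraries from DDA Search Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building calibrated, decoy-appended spectral
    libraries for data-independent acquisition (DIA/SWATH) and parallel
    reaction monitoring (PRM) proteomics from data-dependent acquisition
    search results. Covers peptide fragment-ion chemistry, ingestion of
    peptide-spectrum-match tables and peak lists, discovery of endogenous
    common internal retention-time (CiRT) landmark peptides, robust affine
    retention-time to iRT calibration, consensus spectrum building, top-N
    transition selection, pseudo-reverse decoy generation, parsimony protein
    grouping and library statistics, and export to OpenSWATH transition TSV,
    TraML and scheduled PRM inclusion lists. A seeded simulator of ground
    truth proteomes, runs and spectra supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
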