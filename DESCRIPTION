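Package: apmscall
Title: Interactor Calling for AP-MS Spectral-Count Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tandem-affinity-purification mass
    spectrometry (AP-MS) bait-prey experiments quantified by spectral
    counting. Implements Scaffold-style peptide/protein evidence filtering,
    spectral-count aggregation and between-sample normalization, and a
    combined interactor decision rule (SAM-type weight, one-tailed
    unequal-variance t-test, fold change, and a presence/absence rescue
    criterion for bait-exclusive proteins). Also provides
    ortholog-discriminating-residue assignment of peptides to one of two
    species, gene-level tumour-case overlap arithmetic, and a seeded
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
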