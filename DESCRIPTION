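Package: epifam
Title: Familial Rare-Variant Epistasis Discovery with MB-MDR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for discovering and replicating gene-gene
    interactions in family-based sequencing studies of complex disease.
    Implements site-quality, rarity and non-neutrality filters for
    whole-exome variant calls, selection of variants co-segregating with
    disease (complete penetrance, no phenocopy) in multiplex families,
    gene-set over-representation analysis with a resampled background null,
    a model-based multifactor dimensionality reduction (MB-MDR) engine for
    pairwise epistasis with H/L/O cell labelling, sex adjustment,
    false-discovery-rate control and permutation significance, and
    small-sample AICc model competition against single-variant and additive
    logistic models. A seeded generator of synthetic pedigree and
    case-control genotype data with planted co-segregating variants and
    planted epistatic penetrance structure makes every stage testable
    without access to protected genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
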