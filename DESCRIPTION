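Package: gcpsr
Title: Multilocus Species Delimitation, Diversification Models and DEC
    Ancestral Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for delimiting phylogenetic species in
    fungal species complexes and reconstructing their evolutionary history.
    Implements MEGA-style within- and between-group sequence divergence with
    a reference-calibrated distance cutoff, genealogical concordance
    phylogenetic species recognition (GCPSR) over sets of single-locus gene
    trees, maximum-likelihood fitting of rate-constant and rate-variable
    diversification models with the rate-constancy statistic delta-AIC(RC),
    and dispersal-extinction-cladogenesis (DEC) ancestral range
    reconstruction on ultrametric chronograms.  A synthetic-data module
    (birth-death chronograms, multispecies-coalescent gene trees, HKY
    sequence simulation, neighbor-joining with bootstrap, DEC range
    simulation) provides inputs with known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    phangorn,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
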