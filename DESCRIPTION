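Package: ConStructOTOF
Title: Protein-Centric Pathogenicity Classification of OTOF Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ConStruct approach to classifying single
    amino-acid variants (SAVs) of otoferlin, the protein encoded by OTOF,
    whose pathogenic variants cause auditory neuropathy spectrum disorder
    (ANSD). Variants are encoded by nine protein-centric predictors
    (sequence position, exon number, BLOSUM80 substitution score, C2-domain
    and disordered-region membership, composition-bias and coiled-coil
    flags, and phyloP conservation from the 100-vertebrate and 30-primate
    tracks) and classified with a random forest validated by
    position-ordered five-fold cross-validation. Includes threshold
    calibration from class-conditional score distributions, consensus
    prioritization of variants of uncertain significance (VUS) by mean
    rank score across prediction methods, and a synthetic-data generator
    emulating the class-conditional structure of curated OTOF variant sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
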