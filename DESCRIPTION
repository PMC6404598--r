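Package: dosecall
Title: Bayesian Allele Dosage Calling from Sequencing Read Depth in
    Diploids and Polyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates allele copy number (dosage) in diploid and
    polyploid individuals from allelic read depth, as produced by
    genotyping-by-sequencing (GBS) and RAD-seq protocols. Read counts
    are modelled with a beta-binomial likelihood that accounts for
    cross-sample contamination and overdispersion, and combined with
    genotype priors derived from Hardy-Weinberg equilibrium, partial
    self-fertilization, population structure, linkage disequilibrium,
    or biparental mapping-population designs to yield posterior
    genotype probabilities. Continuous posterior-mean and discrete
    most-probable genotypes can be exported for downstream association
    and prediction analyses. Includes a read-depth simulator and RMSE
    evaluation utilities, plus VCF and CSV import/export and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
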