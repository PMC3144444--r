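Package: gsPersist
Title: Persistence of Genomic Prediction Accuracy Across Generations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the accuracy of genomic and pedigree-based
    estimated breeding values persists over generations in closed breeding
    populations. Provides a gene-dropping simulator of discrete-generation
    populations with tunable trait architecture (proportion of null SNP and
    heritability), SNP and phenotype quality control, pedigree (A) and
    genomic (G) relationship matrices, pedigree BLUP with EM-REML variance
    components, genomic BLUP as a reduced animal model that absorbs records
    of non-genotyped progeny, BayesA and BayesC-pi Gibbs samplers for marker
    effects, cross-generation training/validation designs with the expected
    square-root-one-half decay benchmark, and a linear meta-model relating
    accuracy to heritability, the proportion of null SNP, and generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
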