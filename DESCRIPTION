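Package: gshap
Title: SNP- and Haplotype-Based Genomic Selection for Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction of breeding values from SNP and
    haplotype markers in pedigreed breeding populations. Discovers
    haplotype blocks from linkage disequilibrium with the Gabriel
    confidence-interval algorithm (EM two-locus haplotype frequencies,
    D-prime profile-likelihood bounds, critical r-squared, LD decay),
    phases blocks by multi-locus EM and builds SNP, haplotype and
    combined regressor matrices with 0/1/2 copy coding, and fits five
    Bayesian whole-genome regressions (Bayesian ridge, Bayes A, Bayes B,
    Bayes C-pi, Bayesian LASSO) plus a pedigree animal model by Gibbs
    sampling. Downstream machinery computes genomic variance and
    heritability from marker-effect posteriors, genetic gain under
    truncation selection, cross-validated predictive ability, and
    Tukey-Kramer model comparisons. A synthetic-data generator simulates
    pedigreed populations with block-structured LD, QTL-driven breeding
    values and randomized-complete-block phenotypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
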