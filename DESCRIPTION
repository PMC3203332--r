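Package: aglsnp
Title: Adaptive Group Lasso for SNP Main Effects and Epistatic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disease-associated single nucleotide polymorphisms
    (SNPs) and pairwise epistatic interactions from case-control genotype
    data with an adaptive group lasso logistic regression model. Each SNP is
    coded as a three-level factor and each SNP pair as a nine-level factor;
    whole factors enter or leave the model together under a group sparsity
    penalty whose per-group weights are reweighted adaptively from the
    previous fit. Selected groups are assessed by ridge-stabilized
    likelihood-ratio tests with effective degrees of freedom. Includes
    two-locus penetrance-model simulators (with prevalence and heritability
    summaries), null-data generators, and experiment harnesses estimating
    statistical power and type-I error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
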