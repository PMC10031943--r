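Package: hyborigin
Title: Coalescent ABC Inference of Hybrid Origins and Plant Hydraulic
    Niche Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test hybrid-origin hypotheses for closely related
    plant taxa from reduced-representation SNP panels, and to quantify the
    hydraulic traits used to argue niche divergence of a hybrid lineage.
    Provides VCF import with minor-allele-frequency, missingness and
    Hardy-Weinberg filtering; population diversity and differentiation
    statistics (observed/expected heterozygosity, nucleotide diversity at
    variant sites, Weir-Cockerham F_ST with permutation tests, Nei's
    distance); a backward-in-time coalescent simulator of unlinked biallelic
    SNPs under divergence/admixture scenarios; approximate Bayesian
    computation model choice (direct and multinomial-logistic) and
    local-linear parameter posterior adjustment with logit transform;
    pressure-volume turgor-loss-point extraction and two-phase hydraulic
    capacitance from water-release curves; and seeded synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    nnet,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
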