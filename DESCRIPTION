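Package: lrstructure
Title: Fine Population Structure by Likelihood-Ratio Partition Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based, non-parametric inference of fine population
    structure from unlinked SNV genotypes. Individuals are assigned to K
    subgroups by maximizing the summed per-locus likelihood ratio (half the
    G-statistic) of allele-count by group contingency tables, searched with
    simulated annealing followed by greedy hill-climbing. Includes an
    allele-permutation test for the existence of structure, a second-order
    difference (SOD) discriminant for choosing K, plink-style LD pruning,
    VCF and tab-delimited genotype input, a Balding-Nichols genotype
    simulator with truth labels, and clustering evaluation (adjusted Rand
    index, confusion tables, concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
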