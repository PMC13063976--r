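Package: breedeqtl
Title: Breed-Stratified cis-eQTL Mapping, Effect Sharing, and Trait Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-stratified cis-eQTL analysis in multi-breed
    livestock designs. Implements the full chain from genotype and expression
    preprocessing (variant QC, TPM, TMM normalization, rank-based inverse normal
    transformation, expression-PC covariate selection) through per-breed linear
    mixed-model cis-eQTL mapping with a genomic relationship matrix and
    permutation-calibrated gene-level p-values, classification of eGenes into
    breed-shared and breed-specific categories, cross-breed effect-sharing
    estimates under empirical-Bayes local-false-sign-rate shrinkage, LD-score,
    allele-frequency and conservation summaries, and integration with GWAS
    summary statistics via permutation fold enrichment and approximate-Bayes-
    factor colocalization posteriors. A three-breed synthetic data generator
    (Balding-Nichols genotype divergence, planted shared and specific cis
    effects, polygenic background, GWAS traits with shared causal variants)
    allows the whole pipeline to run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    edgeR,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
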