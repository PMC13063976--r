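# breedeqtl

Breed-stratified *cis*-eQTL mapping, breed-shared/specific eGene
classification, cross-breed effect sharing, and GWAS integration — in one
tested R package.

## What problem this addresses

Commercial livestock breeds (the package's motivating case: Duroc,
Landrace and Yorkshire pigs) differ in complex traits, and part of that
difference is mediated by genetic regulation of gene expression. Mapping
expression QTLs *within each breed separately* — rather than pooling —
reveals which regulatory effects are shared across breeds and which are
breed-specific, and lets both be tested for overlap with trait GWAS
signals. `breedeqtl` is for quantitative geneticists who want that whole
chain as composable, pipe-friendly functions with tibble outputs: from raw
counts and dosages to eGene lists, sharing estimates, enrichment folds and
colocalization posteriors, plus a three-breed simulator with planted
ground truth for validating every step.

## The model at the core

Per breed, tissue and gene, expression is modelled with the linear mixed
model

y = Xα + sβ + g + e,  g ~ N(0, G σ²_g),  e ~ N(0, I σ²_e)

with y the inverse-normal-transformed expression, s the mean-centered
dosage of the tested variant (0/1/2), and
G = MM′ / (2 Σᵢ pᵢ(1−pᵢ)) the genomic relationship matrix from
genome-wide post-QC variants. Variance components are REML-estimated per
gene in the eigenbasis of G; every variant within ±1 Mb of the TSS gets a
Wald test with variance components fixed at the null fit; gene-level
p-values come from permutations of y ((1 + #{perm min-p ≤ observed})/(k+1));
eGenes are called at Benjamini–Hochberg q < 0.05. Downstream: eGene
classification by the number of breeds detecting them; effect sharing by
sign and factor-2/factor-4 magnitude agreement among effects with local
false sign rate < 0.05 under empirical-Bayes shrinkage; GWAS fold
enrichment against resampled non-significant control SNP sets; and
five-hypothesis colocalization from Wakefield approximate Bayes factors
(colocalized when PP.H4 > 0.8).

## Worked example

Simulate a small three-breed cohort, map each breed, classify eGenes and
estimate cross-breed sharing:

```r
library(breedeqtl)
library(dplyr)

cfg <- sim_config(n_per_breed = 80, n_variants = 1200, n_genes = 60,
                  chrom_length = 2.4e7, seed = 7)
g   <- simulate_genotypes(cfg)
sim <- simulate_expression(g, cfg)
qc  <- genotype_qc(g, "per_breed")

maps <- lapply(c("Duroc", "Landrace", "Yorkshire"), function(b)
  map_breed_eqtl(qc$genotypes, sim$expression, b, k_perm = 200, seed = 7))
names(maps) <- c("Duroc", "Landrace", "Yorkshire")

maps$Duroc$summaries |> filter(is_egene) |>
  select(gene, lead_variant, lead_beta, p_gene, q_value) |> head(4)
#>   gene     lead_variant lead_beta  p_gene q_value
#> 1 gene0001 snp00017        -1.13  0.00498 0.00905
#> 2 gene0002 snp00056         0.880 0.00498 0.00905
#> 3 gene0003 snp00068        -1.27  0.00498 0.00905
#> 4 gene0004 snp00118         1.10  0.00498 0.00905
```

Each row is one gene's strongest cis association: `lead_beta` is the
allele-dosage effect on the INT expression scale, `p_gene` the
permutation-calibrated gene-level p (its floor here is 1/201), and
`q_value` the BH-adjusted value used for the eGene call.

```r
cl <- classify_egenes(lapply(maps, `[[`, "summaries"), tissue = "sim")
classification_summary(cl)$per_breed
#>   breed     n_egenes n_shared shared_fraction
#> 1 Duroc           39       37           0.949
#> 2 Landrace        44       41           0.932
#> 3 Yorkshire       40       34           0.85

pe <- pair_lead_effects(maps$Landrace, maps$Yorkshire,
        genes = cl$gene[cl$egene_Landrace & cl$egene_Yorkshire])
s1 <- shrink_lfsr(pe$b1, pe$se1); s2 <- shrink_lfsr(pe$b2, pe$se2)
pairwise_sharing(tibble(b1 = s1$posterior_mean, b2 = s2$posterior_mean,
                        lfsr1 = s1$lfsr, lfsr2 = s2$lfsr),
                 c("Landrace", "Yorkshire"))
#>   breed_pair         n_effects prop_sign prop_mag2 prop_mag4
#> 1 Landrace-Yorkshire        31         1     0.935     0.935
```

So of the 31 Landrace–Yorkshire shared eGenes with a significant shrunken
effect, all have direction-concordant effects and 93.5% agree within a
factor of two — consistent with the generator, which plants
sign-concordant equal-variance-share effects for shared genes.
`autoplot()` methods exist for every result type (`de_result`,
`eqtl_summary`, `egene_classification`, `sharing_estimate`,
`enrichment_result`, `coloc_result`), and `tidy()`/`glance()` for fitted
`lmm_fit` objects.

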