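---
title: "Breed-stratified cis-eQTL mapping with breedeqtl: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-stratified cis-eQTL mapping with breedeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`breedeqtl` implements a population-stratified cis-eQTL workflow for
multi-breed designs such as a balanced panel of Duroc, Landrace and
Yorkshire pigs: each breed is mapped separately with a linear mixed model,
gene-level significance is calibrated by permutation, eGenes are classified
into breed-shared and breed-specific sets, effect sharing across breeds is
quantified under empirical-Bayes shrinkage, and the resulting eGene sets
are integrated with GWAS summary statistics through fold-enrichment
resampling and colocalization posteriors. This vignette documents the
statistical models, the parameters that matter, and the choices we made
where the design was genuinely open.

## The mapping model

For one gene in one breed and tissue, expression is modelled as

$$ y = X\alpha + s\beta + g + e, \qquad
   g \sim N(0, G\sigma^2_g), \quad e \sim N(0, I\sigma^2_e), $$

where $y$ is the inverse-normal-transformed expression vector, $X$ holds
an intercept plus optional covariates, $s$ is the mean-centered dosage of
the variant under test (0/1/2 alternate-allele counts), and $G$ is the
genomic relationship matrix
$G = MM' / \left(2\sum_i p_i(1-p_i)\right)$ built from all genome-wide
post-QC variants of the breed ($M$ column-centered dosages, $p_i$ allele
frequencies). We deliberately include the cis region in $G$ (no
leave-one-chromosome-out): that matches the plain definition above, and at
the sample sizes this package targets the proximal contamination effect is
negligible relative to permutation calibration.

`fit_null_lmm()` estimates $(\sigma^2_g, \sigma^2_e)$ by REML in the
eigenbasis of $G$: the variance ratio $\delta = \sigma^2_g/\sigma^2_e$ is
profiled on a 23-point grid over $\log_{10}\delta \in [-6, 5]$ (plus the
boundary $\delta = 0$) and refined by golden-section search; $\alpha$ is
the GLS solution at the optimum. Numerically non-PSD GRMs are repaired by
flooring eigenvalues at $10^{-8}$ with a warning.

During the cis scan (`test_cis()`), variance components are held fixed at
the null fit and each variant gets a Wald t-test in the rotated, weighted
space (df $= n - c - 1$). Re-estimating the variance components per
variant changes nothing detectable at cis effect sizes but costs an order
of magnitude more time; with $G = I$ and no covariates the scan reduces
exactly to OLS simple regression, which the test suite asserts at 1e-8.

The cis window is $[\mathrm{TSS} - 10^6, \mathrm{TSS} + 10^6]$, both
boundaries inclusive, anchored at the TSS with strand ignored.

## Permutation calibration and eGene calling

`permutation_gene_p()` permutes $y$ (fresh rotation per permutation,
variance components fixed), records each permutation's minimum nominal p
over the window, and reports the +1-smoothed tail probability
$(1 + \#\{\min p_{perm} \le \min p_{obs}\})/(k+1)$. A Beta-distribution
fit to the permuted minima (maximum likelihood) is available as a smoothed
alternative (`beta_approx = TRUE`), useful when $k$ is small relative to
the target resolution. We default to $k = 1000$ permutations; the test
suite and the acceptance script use $k = 200$, which resolves gene-level
p-values to 1/201 — sufficient for BH calling at q < 0.05 over hundreds of
genes.

`call_egenes()` applies Benjamini–Hochberg across genes within a
tissue-by-breed run and flags eGenes at $q < 0.05$ (strict). For each
eGene the nominal-p threshold for its significant cis-eQTLs is the
empirical quantile (type 1) of that gene's permuted minima at the largest
gene-level p still passing the q cutoff.

## Preprocessing

The chain in `preprocess_expression()` is: counts → TPM (`counts_to_tpm`,
length-normalized rates scaled to $10^6$ per sample) → low-expression
filter (drop genes with TPM ≤ 0.1 in *strictly more than* 80% of samples)
→ TMM normalization of the filtered counts (edgeR's trimmed mean of
M-values: 30%/5% trims on M and A, precision weights, reference sample by
the upper-quartile rule, factors rescaled to unit geometric mean) →
per-gene rank-based inverse normal transform with the Blom offset,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, ties receiving average ranks. The Blom
constant is a convention choice; any offset yields the same ranks, and
downstream results depend on the values only through smooth monotone
effects.

Genotype QC (`genotype_qc()`) has two stages with deliberately different
boundary conventions: a pooled stage keeping variants with MAF ≥ 0.05 and
MAC ≥ 6 across all samples, and a per-breed stage keeping, within each
breed, MAF > 0.01, MAC > 6 and heterozygote fraction < 0.99 (all strict),
then intersecting the surviving sets across breeds so downstream analyses
use one common panel. The suite pins the boundary behaviour (per-breed
MAC = 6 fails, 7 passes).

`select_expression_pcs()` computes sample-space PCs of the
gene-standardized matrix and selects the smallest $n \ge 1$ such that the
cumulative-PVE increments from PC $n{+}1$ and PC $n{+}2$ are *each* below
0.1% of PVE($n$). The rule could also be read as a single combined
two-step increment; we implement the conjunction reading and expose
`rule = "combined"` as a switch. When no elbow exists the function falls
back to min(10, samples − 2) PCs with a warning. PCs are computed after
gene filtering (recomputation on the filtered matrix is the only
self-consistent option when filtering changes the gene set). Note that on
small synthetic gene panels (hundreds of genes) expression PCs span much
of the sample space and can absorb genuine cis signals; with no batch
structure simulated, the packaged analyses therefore map without PC
covariates, while the selector itself is exercised on constructed spectra.

## Differential expression

`differential_expression()` contrasts one breed against the other two
pooled, per gene, on log2(TPM + 1): difference of group means as the
log2 fold change, pooled-variance two-sided t-test, BH correction, and the
compound significance rule |log2FC| > 1 *and* FDR < 0.05. A moderated
(empirical-Bayes) variance estimator would change borderline genes only;
the rule here is threshold-driven and the +1 pseudo-count stabilizes the
log at zero counts.

## Sharing, shrinkage, and population descriptors

eGene classification is a partition by the number of breeds in which the
gene passes q < 0.05: specific (one), two-breed shared, three-breed
shared, non-eGene.

Cross-breed effect sharing uses per-condition empirical-Bayes shrinkage
(`shrink_lfsr()`): a normal-means model with a point mass at zero plus
zero-mean normal components on a geometric scale grid (from min(se)/10 to
2·max|betahat|), weights fitted by EM on the marginal likelihood. The
local false sign rate of an effect is the smaller of the posterior
probabilities of being ≤ 0 or ≥ 0 (the point mass counts toward both). A
full multivariate analysis with data-driven covariance across breeds would
pool information between conditions; the quantities reported here — sign
concordance and factor-2/factor-4 magnitude agreement among
LFSR-significant effects — are computable from per-condition posteriors,
and a matrix hook allows substituting externally computed posteriors.

`pairwise_sharing()` restricts to effects with LFSR < 0.05 in *at least
one* breed of the pair (gating on both is available via `gate = "both"`)
and computes proportions on posterior means by default. Effects are
anchored on one common variant per gene (`pair_lead_effects()`: the lead
of the breed with the stronger gene-level signal, looked up in both
breeds), which keeps the comparison a property of one cis-eQTL rather
than of two different LD proxies.

LD scores are sums of pairwise dosage $r^2$ within a region, self term
included (so scores ≥ 1, matching the common tool convention); per-breed
MAF is the folded allele frequency; gene conservation averages a
0-based half-open score track over the gene body and reports a mean only
when at least 50% of the gene's length is covered.

## Trait integration

Traits are retained when their minimum GWAS p-value is ≤ 5×10⁻⁸. eGene
regions are TSS ± 1 Mb intervals clipped at position 1 and merged per
chromosome, so a SNP between two overlapping windows counts once.
`enrichment_permutation()` compares the in-region proportion of
significant SNPs against equal-size control sets sampled *without
replacement* from the non-significant pool (unmatched for MAF/LD — the
plainest reading of the resampling scheme; matched sampling is a
documented extension point), reporting fold enrichment against the mean
control proportion and a +1-smoothed empirical p. Because the control
proportion is a discrete statistic with ties, the empirical p is slightly
conservative; calibration checks therefore look at its mean and rejection
rate rather than a continuous-distribution comparison.

Colocalization (`coloc_abf()`) computes per-SNP Wakefield log approximate
Bayes factors, $\tfrac12\log(1-r) + \tfrac12 r z^2$ with
$r = W/(V + W)$, for both traits and enumerates the five standard
hypotheses with per-SNP priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$;
a pair is colocalized when PP.H4 > 0.8. The prior effect scale defaults
to 0.15 (the common convention for quantitative traits) and is
overridable per trait: for eQTL effects measured on the INT scale, where
detected lead effects are of order 1, an effect-scale-matched prior (for
instance the empirical sd of detected lead effects) markedly improves the
separation of H3 from H1/H2 and is what the packaged validation run uses
on the eQTL side.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the emulated study: 3 breeds × 100
individuals, one synthetic chromosome of 50 Mb carrying 2,500 evenly
spaced SNPs and 200 genes, breed divergence Fst = 0.2 (the order reported
between commercial pig breeds), AR(1) latent-field LD with ρ = 0.5
between adjacent variants (~20 kb spacing), 70% of genes with a
breed-shared cis effect (split 2:1 between three-breed and two-breed
sharing), 20% breed-specific, 10% null, cis variance share 0.3, polygenic
share 0.3, GWAS n = 10,000 with 0.5% variance per trait locus and half of
the trait loci sharing the eQTL causal variant. One chromosome suffices
because every procedure in the pipeline is per-window or
per-chromosome-agnostic.

Key generator mechanics:

* **Genotypes.** Ancestral frequencies uniform on [0.05, 0.95]; per-breed
  frequencies Balding–Nichols Beta with variance $F p(1-p)$; haplotypes by
  thresholding an AR(1) Gaussian field, dosage as the sum of two
  haplotypes. Founders are unrelated — within-breed relatedness of real
  nucleus populations is not emulated, so the GRM's role here is to absorb
  the simulated polygenic background rather than pedigree structure.
* **Expression.** Latent trait per breed = scaled causal dosage +
  GRM-structured polygenic term + Gaussian noise (unit total variance);
  counts = Poisson with a log-normal gene baseline × exp(latent) ×
  log-normal library factor. Only monotonicity of the link is relied on;
  the Poisson stage attenuates the realized cis variance share on the INT
  scale by a few points below the planted 0.3.
* **Causal placement.** Causal variants (and the distinct trait variants
  below) are drawn among variants common (MAF ≥ 0.05) in every breed, so
  planted signals remain inside the per-breed QC'd common panel the mapper
  actually scans. Shared genes share one causal variant and sign across
  their breeds, with per-breed effect sizes set to the common variance
  share.
* **GWAS.** Trait loci are a sparse selection of effect genes whose causal
  variants are ≥ 2.5 Mb apart — real trait signals are sparse on a
  chromosome, and the enumeration colocalization model assumes one causal
  variant per window. A fraction `gwas_frac_coloc` of selected genes uses
  the eQTL causal variant; the rest plant a distinct cis variant with
  r² < 0.2 to it. Marginal effects propagate through genotype
  correlations within ±2 Mb of each causal (LD is local under the AR(1)
  field; sample correlations beyond that are reference-panel noise), and
  estimates are drawn independently as $N(\beta_{marginal}, se^2)$ with
  $se^2 = 1/(2np(1-p))$. Several traits can be drawn from one cohort via
  the `seed` argument.

Passing the packaged recovery tests therefore demonstrates correct
statistical behaviour under this generative model — calibrated nulls,
recovery of planted effects, sharing and colocalization discrimination —
not robustness to features the generator omits: cell-type heterogeneity,
batch structure, pedigree relatedness, non-Poisson overdispersion,
multi-signal cis architecture, or genotyping error.

## Problem sizes and runtime

The suite and `scripts/acceptance.R` run the full chain at 100 individuals
per breed, 200 genes, 2,500 variants and 200 permutations per gene (about
half a minute per full three-breed mapping on one core), 50 REML
replicates for heritability recovery on the pooled 300-sample GRM, 10
simulated traits (~150 coloc events), and 50–200 resampled traits for
enrichment calibration. These sizes were chosen so each quantity's
Monte-Carlo error is small relative to the tolerance being asserted.

## Known limitations

* Only additive dosage coding; no dominance or genotype-by-breed
  interaction terms — breeds are analysed strictly separately.
* Single-signal colocalization; conditionally independent secondary
  cis signals are not modelled.
* The LFSR shrinkage is condition-by-condition; cross-condition
  correlation of effects is used only through the common-variant pairing,
  not through a joint prior.
* Mean-imputation of sporadic missing genotypes is adequate for the
  near-complete data this pipeline expects, not for high missingness.
* The enrichment control sampling is not MAF- or LD-matched.
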