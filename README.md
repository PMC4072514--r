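# temqtl

Genetic regulation of CD4+ effector memory T (T<sub>EM</sub>) cells, before
and after T-cell receptor stimulation: an R toolkit for cis-eQTL mapping
with permutation empirical p-values, automated cytometry quantification,
cell-trait GWAS, and a proliferation-potential gene signature.

## Who this is for

Immunogenetics groups that profile a purified immune cell population across
resting and stimulated states and want one tested pipeline for the standard
questions: which genes have local genetic regulation in which state, do
candidate autoimmune risk alleles (rheumatoid arthritis, type 1 diabetes,
celiac disease) explain those signals, do genetics or age/gender shape the
population's abundance and proliferative response, and does baseline
expression predict that response. Because such cohorts are rarely
redistributable, the package ships a seeded synthetic-cohort generator that
reproduces the statistical structure every stage assumes, with ground-truth
bookkeeping so calibration and power are testable properties rather than
hopes.

## The models at the core

**Cis-eQTL scan.** For each gene and state, every SNP within 250 kb of the
TSS is tested with

&nbsp;&nbsp;&nbsp;&nbsp;expression = β₀ + β₁·dosage + β₂PC₁ + … + β₆PC₅ + β₇·gender + ε,

on natural-log expression, so exp(β₁) is the fold change per allele.
Empirical p-values come from permutations of the covariate residuals (one
shared stream per gene, preserving local LD): per SNP,
p = (1 + #{permuted p ≤ observed p}) / (n_perm + 1), plus a family-wise
regional version (`gene_perm_p`, the region-minimum statistic) that feeds
Benjamini–Hochberg selection across genes at FDR 5%. Conditional analysis
appends a candidate allele's dosage to the covariates and asks whether any
regional signal survives; state-specificity is tested with
z = (β_stim − β_rest)/√(SE²_rest + SE²_stim) against a standard normal.

**Cytometry.** T<sub>EM</sub> abundance is gated automatically by a
seven-component trivariate Gaussian mixture over CD45RA/CD45RO/CD62L,
EM-fitted from a labelled template; abundance is the TEM posterior mass as
a percentage of all non-debris mass. Proliferation is deconvolved from CFSE
dye dilution: a constrained one-dimensional Gaussian mixture with equal
peak-to-peak spacing (initialized at log10 2) and shared variance yields
division weights w₀..w₅, the division index DI = Σk·w_k and the
proliferation index PI = Σ_{k≥1}k·w_k / Σ_{k≥1}w_k.

**Cell-trait GWAS and enrichment.** Per-SNP OLS with gender, age and five
genotype PCs (plus measured abundance for proliferation traits), genomic
control λ_GC diagnostics, QQ tables with order-statistic confidence bands,
and an exact one-tailed binomial test for enrichment of nominal
associations among disease SNP–gene pairs.

**Proliferation signature.** Genes are screened by Pearson correlation of
baseline expression with PI against a permutation null (p < 0.01,
two-tailed); selected genes get ±1 weights by correlation sign, individuals
are scored by the standardized weighted sum, and the gene count, split-half
cross-validation and cross-visit replication are all evaluated against
permutation nulls.

**Epigenome overlap.** For lead SNPs and their LD partners (r² ≥ 0.8), the
distance to and height of the nearest H3K4me3 peak (BED, half-open
coordinates), compared between SNP sets with one-sided Mann–Whitney tests.

## Worked example

```r
library(temqtl)

cfg    <- sim_cohort_config(n_individuals = 150, n_snps = 400,
                            n_genes = 40, seed = 42)
cohort <- simulate_cohort(cfg)

covs   <- cohort$covariates[, c("individual_id", "gender", paste0("PC", 1:5))]
planted <- head(cohort$truth$eqtl_map, 4)
genes   <- cohort$genes[cohort$genes$gene_id %in% planted$gene_id, ]
leads   <- scan_all_genes(genes, cohort$genotypes, cohort$stim, covs,
                          n_perm = 1000, seed = 42, state = "stim")
fdr_select(leads, q = 0.05)
#> # A tibble: 4 x 13 (selected columns)
#>   gene_id snp_id     beta  fold gene_perm_p  fdr_q significant
#> 1 gene018 snp00140 -0.182 0.834     0.195   0.390  FALSE
#> 2 gene019 snp00287 -0.264 0.768     0.00899 0.0360 TRUE
#> 3 gene024 snp00031 -0.181 0.834     0.405   0.539  FALSE
#> 4 gene025 snp00238 -0.140 0.869     0.759   0.759  FALSE
```

Four genes carry planted cis-eQTLs; only `gene019` (planted β = −0.30 at
`snp00288`) clears FDR 5% at n = 150 — its lead SNP `snp00287` is an LD
partner of the causal one, and exp(−0.264) = 0.77 is the estimated fold
change per allele. The weaker planted effects (|β| ≤ 0.17) are below power
at this sample size, which is the expected behaviour, not a failure.

The cross-state test on two printed effect estimates, and a CFSE fit:

```r
state_difference_test(-0.366, 0.085, -0.805, 0.071)
#>       z   p_delta
#>   -3.96 0.0000738

ws <- simulate_cfse_experiment(c(0.5, 0.25, 0.25), cfg, n_events = 10000)
quantify_proliferation(ws)$fits[[1]]
#> <cfse_fit> 10000 events: mu0 = 2.501, spacing = 0.302, sigma = 0.080
#>   weights: 0.498 0.259 0.243 0.000 0.000 0.000
#>   DI = 0.745, PI = 1.484 (converged)
```

A stimulated effect of −0.805 versus a resting −0.366 differs at
p ≈ 7.4×10⁻⁵; the dilution fit recovers the planted division weights
(0.5, 0.25, 0.25) to within ~0.01 and the halving spacing log10 2 ≈ 0.301.

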