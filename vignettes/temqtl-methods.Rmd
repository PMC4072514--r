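---
title: "Methods: models, estimators and design choices in temqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in temqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temqtl)
```

temqtl analyses a purified CD4+ effector memory T (TEM) cell population
measured in two states — resting and after anti-CD3/CD28 (TCR)
stimulation — in a genotyped cohort. This vignette is the package's own
account of the statistics it implements: the models, their assumptions,
the tunable parameters, the numerical choices, and the places where the
design was genuinely open and we had to decide.

## 1. The cis-eQTL model

For one gene, one state and one SNP we fit, by ordinary least squares,

$$y_i = \beta_0 + \beta_1 g_i + \sum_{k=1}^{5}\gamma_k \mathrm{PC}_{ki}
 + \gamma_6\,\mathrm{male}_i + \varepsilon_i,$$

where $y$ is normalized expression on the natural-log scale and $g$ the
allelic dosage in $[0,2]$. The analytic p-value is the two-tailed t-test
on $\beta_1$ with $n-8$ residual degrees of freedom. Because $y$ is a log,
$e^{\beta_1}$ is a multiplicative fold change per allele: a stimulated
effect of $\beta_1=-0.805$ is a fold of $0.45$, i.e. each alternate allele
roughly halves expression. The genotype principal components are computed
EIGENSTRAT-style — dosages centred at $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$, top eigenvectors of the individual covariance —
and absorb population stratification; gender is the only non-genetic
covariate in the expression model.

Assumptions: additivity in dosage, homoscedastic Gaussian residuals
(approximately met by log-scale normalized expression), and covariates
sufficient to remove confounding. Imputed fractional dosages are accepted
wherever hard calls are; the panel QC step removes SNPs with MAF < 0.01 or
imputation quality < 0.4 (both strict inequalities, so a SNP exactly on a
threshold survives).

### Permutation empirical p-values

Within each gene's cis window (TSS ± 250 kb, both boundaries inclusive,
strand ignored) the SNPs are heavily correlated, so analytic p-values
cannot be compared across genes of different LD content. We residualize
expression on the covariates once and permute those residuals; every cis
SNP is re-tested against each of the `n_perm` permutations (one stream per
gene, derived by hashing the gene id with the master seed, so serial and
parallel schedules agree). Two summaries are produced:

* **per-SNP empirical p** — the add-one-smoothed fraction of permutations
  in which that SNP's permuted p is at or below its observed analytic p;
  its floor is $1/(n_\mathrm{perm}+1)$;
* **gene-level `gene_perm_p`** — the same comparison applied to the
  regional *minimum* p across SNPs. This family-wise quantity is uniform
  under the gene's null regardless of how many SNPs the window holds.

`fdr_select()` applies Benjamini–Hochberg across genes (within state) to
`gene_perm_p` by default. Applying BH to the lead SNP's *per-SNP*
empirical p instead would be anti-conservative: the lead is the minimum of
many correlated, marginally uniform values, so null genes would reach
small p by multiplicity alone. We keep the per-SNP quantity on every
output row (it is the natural per-variant summary and is what conditional
analysis reports), but gene discovery uses the calibrated regional p. The
package asserts both calibration (uniform p under the global null) and
realized false-discovery proportion on cohorts with planted truth in its
test suite.

Two permutation modes exist. The default re-tests permuted residuals
against the *covariate-residualized* dosage via the Pearson correlation —
after residualizing once, each permutation costs one matrix product. Using
raw dosage here would attenuate the permuted statistics, because genotype
PCs overlap every SNP slightly, and the empirical p would be deflated; the
residualized form keeps the permuted and observed statistics on the same
footing. An `permute = "exact"` mode refits the full model per permutation
for verification; the suite checks the two agree.

Ties in the lead-SNP choice are broken by smaller analytic p, then smaller
position. `n_perm` below 100 is refused (the resolution would be
meaningless); the study-scale default is 10,000, and the package's own
simulations use 500–1,000 to keep suites fast — a resolution choice, not a
statistical one, since every comparison involving those runs uses
thresholds well above the corresponding floors.

### Conditional analysis and state specificity

`conditional_scan()` appends the candidate (e.g. disease-associated)
allele's dosage to the covariates and re-runs the scan. The conditioned
SNP and any perfect proxies become numerically untestable (their
residualized dosage is ~0) and are dropped. A region is `fully_explained`
when the residual scan's `gene_perm_p` is at or above 0.05 — again the
family-wise form, since "no residual SNP below 0.05" read per-SNP would be
false for almost any multi-SNP region by chance.

Effects in the two states are compared with
$z = (\beta_\mathrm{stim}-\beta_\mathrm{rest}) /
\sqrt{SE_\mathrm{rest}^2+SE_\mathrm{stim}^2}$, two-tailed against a
standard normal. The states are treated as independent samples; since the
same individuals contribute to both, shared noise would make the test
conservative rather than liberal. Its type-I rate on independently
generated equal-effect states is asserted in the suite.

## 2. Cytometry quantification

### Template-guided gating

Events are trivariate transformed intensities (CD45RA, CD45RO, CD62L). A
seven-component full-covariance Gaussian mixture is fitted by EM,
initialized at a labelled `population_template`; the TEM component is
CD45RA−/CD45RO+/CD62L-low and one component is debris. After convergence,
fitted components are matched one-to-one back to template labels by
Mahalanobis distance between means under the template covariances.
Abundance is 100 × (TEM posterior mass)/(non-debris posterior mass) — the
debris exclusion is part of the definition, not a post-hoc filter.

Numerical choices: log-likelihood convergence tolerance 1e-6, cap 200
iterations, event floor 350 (≈50 per component), covariance determinant
floor 1e-12 below which a collapsing component is re-seeded from the
template once and the fit flagged failed on a second collapse; a small
ridge (1e-8) keeps covariance updates positive-definite. `max_iter = 0`
returns the template itself with posteriors under it, which is also how
the E-step is cross-checked against an independent mixture implementation
in the tests. The per-iteration log-likelihood trace is retained and its
monotonicity asserted on every fit in the suite.

### CFSE dilution deconvolution

CFSE halves per division, so on a log10 axis generation $k$ peaks at
$\mu_0 - k d$ with $d \approx \log_{10} 2 \approx 0.301$. Pooled resting
wells estimate $(\mu_0, \sigma_0)$ as a single Gaussian (sample mean/SD;
bimodal input still returns pooled moments — documented, since a failed
stimulation control is a QC problem upstream of fitting). The stimulated
wells are fitted with at most six components ($k = 0..5$), equal spacing,
shared variance, and weights free on the simplex (zeros allowed), under
box constraints: $\mu_0^*\in \mu_0\pm\sigma_0$ (the resting peak
*initializes and brackets* the undivided location rather than freezing
it), $d \in [0.7, 1.3]\log_{10}2$.

The optimizer is a constrained EM: responsibilities give the weight
update in closed form; $(\mu_0^*, d)$ solve a weighted least-squares
system, projected into their boxes by two coordinate passes; the shared
variance is the responsibility-weighted mean squared residual (floored at
1e-8). We chose this over a generic quasi-Newton on a transformed
parameterization because every update is closed-form, the likelihood
ascent is monotone by construction (a numerical guard stops the iteration
if a projection ever breaks ascent beyond 1e-8), and there are no
step-size heuristics to tune. Convergence is a log-likelihood gain below
1e-6 or 500 iterations; two additional random restarts of the weights are
run and the best log-likelihood kept, with restart stability asserted in
the suite, along with a grid-search likelihood oracle for two-component
fits.

From the fitted weights, DI $= \sum_k k\,w_k$ and PI
$= \sum_{k\ge1} k\,w_k / \sum_{k\ge1} w_k$; PI is flagged undefined when
the divided mass is below 1e-6 (a flag, not an error — an undivided well
is a legitimate observation). The identity PI(1−w₀) = DI holds exactly
and is asserted. Replicate stimulated wells are fitted separately and
DI/PI averaged; the alternative (joint fit across wells) would share
nuisance parameters across wells that can genuinely differ in staining
intensity, so per-well fitting is the safer default.

## 3. Cell-trait GWAS, λ_GC and enrichment

`genome_scan()` runs per-SNP OLS of a quantitative trait on dosage plus
covariates — gender, age and five genotype PCs for abundance; those plus
measured abundance for proliferation traits — with genome-wide
significance at 5×10⁻⁸ and a suggestive band at 5×10⁻⁵. Monomorphic SNPs
are skipped and logged. λ_GC is the median 1-df chi-square quantile of the
p-values divided by 0.4549364; it is 1 ± 0.01 on 10⁵ uniform p-values and
scales linearly under chi-square inflation (both asserted). QQ confidence
bands come from the Beta(i, n−i+1) distribution of uniform order
statistics.

Enrichment of nominal associations among disease SNP–gene pairs uses the
exact upper binomial tail: with 182 pairs at α = 0.05 the expectation is
9.1 ("about nine"), and P(X ≥ observed) is summed exactly rather than
normal-approximated — at these sizes the approximation is off by orders of
magnitude in the far tail, and the exact tail has a brute-force oracle in
the tests.

## 4. The proliferation-potential signature

Baseline (resting) expression is screened gene-by-gene by Pearson
correlation with the proliferation index; the permutation p (shared
permutations of the PI vector across genes, add-one smoothing) is
two-tailed. Genes below the threshold (default 0.01) enter the signature
with weight sign(r); individuals are scored by
$\mathrm{score}_i=\sum_g w_g z_{g}(i)$ with per-gene standardization
across the scored individuals. Standardization is a deliberate choice:
raw abundance-scale sums are dominated by the most highly expressed genes,
making the unstandardized weighted sum degenerate across platforms;
`standardize = FALSE` is available for sensitivity analysis.

The count of selected genes is referred to a permutation null: for each
permutation of PI, genes passing the threshold are counted using the
analytic t-based p inside the loop. A permutation-within-permutation
would cost millions of fits for identical inference at cohort sizes near
200, where the analytic and permutation per-gene p agree closely; the
suite verifies the resulting count distribution against its
Binomial(G, 0.01) oracle on independent null genes. Split-half
cross-validation uses a single random unstratified half-split per seed,
builds the signature on one half and evaluates the held-out correlation
with a one-tailed permutation p, in both directions; cross-visit
replication trains on each visit and scores the other for individuals
sampled twice. Selection-then-evaluation on the same individuals
overestimates r relative to held-out evaluation, and the suite asserts
that overfitting direction.

## 5. H3K4me3 proximity

Peaks arrive as BED (0-based half-open) with a height score and optional
summit offset; SNP positions are 1-based. The conversion is centralized:
distance is the number of bases strictly between SNP and peak (0 inside
or adjacent, the GenomicRanges convention; a SNP at 1-based 1,000 and a
peak [1100, 1200) are 100 bases apart). For an index SNP and its LD
partners (r² ≥ 0.8), the set-minimum distance and that peak's height are
reported, ties broken toward the taller peak; summit distance is also
emitted because edge- and summit-distance answer slightly different
questions and the choice between them is not settled. Set comparisons use
the one-sided Mann–Whitney test: exact when both groups have ≤10 untied
values, otherwise the normal approximation with tie and continuity
corrections; all-tied inputs return p = 1 with a degenerate flag.

## 6. The synthetic-cohort generator

The generator exists so that every downstream stage can be tested against
known truth. Its defaults encode the cohort structure the package targets:

* **Phenotypes.** TEM abundance mean 9.57%, SD 4.85%, increasing 0.11
  percentage points per year of age, men 2.22 points above women
  (residual noise absorbs the remaining marginal variance); division
  index mean 1.46, SD 0.35; proliferation index mean 2.16, SD 0.21. Ages
  are uniform on 19–57 and gender is Bernoulli(134/225 female), matching
  the cohort description the defaults derive from. Abundance is truncated
  to (0, 100).
* **Cohort scale.** 174 individuals (complete-data subset) and 215
  assayed genes by default; the SNP panel defaults to 1,000 markers laid
  out in LD blocks at 5 kb spacing — a desk-scale panel with the local
  structure the cis machinery needs, not a genome-wide map.
* **Genotypes.** Balding–Nichols: ancestral frequencies uniform on the
  MAF range, subpopulation frequencies Beta-distributed at fixation index
  F (default two subpopulations, F = 0.01 — visible to PCA, small enough
  to mimic within-ancestry structure). LD by first-order haplotype
  copying within blocks (copy probability 0.9), giving adjacent-pair r²
  near 0.8 and geometric decay; block boundaries are LD-free. Dosages are
  hard calls; the Weir–Cockerham estimator on generated panels is the
  differentiation oracle in the tests.
* **Expression.** Natural-log scale directly (the model's scale), with
  per-gene gender and PC effects, residual SD 0.5, and planted cis-eQTLs
  within 250 kb of each chosen gene's TSS: a fraction 46/205 of genes get
  an effect (β ~ N(0, 0.5²)), of which 11/46 are active in exactly one
  state — both fractions taken from the observed disease-locus gene
  counts.
* **Signature and proliferation.** A 17-gene signature (15 negative, 2
  positive) loads on a shared per-individual factor in resting
  expression (loading 0.6). Both DI and PI load on that factor
  (coefficient 0.6) — they are two read-outs of the same dilution
  experiment, so the factor should drive both directly; DI additionally
  carries a negative abundance term (−0.25), and a residual coupling sets
  the DI–PI correlation to 0.7. With these defaults the per-gene
  correlation of a signature gene with PI is ≈0.3–0.4 and the aggregate
  score correlation ≈0.45–0.6, the regime in which a ±1-weighted
  signature is detectable but not trivial at n ≈ 180.
* **Cytometry.** Per-individual CFSE division weights are
  Binomial(5, DI/5) — so the planted DI is exactly the mixture mean — and
  the flow template's TEM share equals the individual's planted
  abundance, keeping every truth inside the search space of the stage
  meant to find it.

What the generator does **not** emulate: realistic genome-wide LD maps and
recombination hotspots, raw NanoString counts and their normalization
artifacts (an optional count layer exists for I/O exercises only), FCS
binary files, spillover/compensation, batch structure, or relatedness.
Passing tests therefore demonstrate that the estimators are correct and
calibrated under the stated models — not that those models capture every
pathology of real cytometry or expression data.

## 7. Problem sizes in the shipped suites

The test and acceptance code exercise the pipeline at sizes chosen to make
sampling error small relative to the tested tolerances while keeping runs
desk-scale: 5,000-fit calibration batteries, 10⁵ p-values for λ_GC,
100-replicate recovery runs at n = 200 with 500–1,000 permutations per
gene, 50-replicate FDR runs over 40-gene panels, 10,000–20,000-event
cytometry fits, and a 182×215 null matrix for the signature count null.
These are the package's own choices of demonstration scale; every
interface accepts the study-scale values (10,000 permutations, genome-wide
panels) unchanged.

## 8. Known limitations

* Trans-eQTLs, splice/isoform-level effects and epistasis are out of
  scope, as is genotype imputation itself (only post-imputation QC
  filters are implemented).
* The expression normalization that produces the log-scale matrix is
  accepted as input, not reproduced.
* The cross-state z-test ignores the within-individual pairing of states
  (conservative under shared noise).
* The CFSE model fixes a maximum of five divisions; highly proliferative
  samples beyond that fold into the last component.
* `fully_explained` is a calibrated regional statement at α = 0.05; it is
  not evidence that the conditioned variant is causal, only that no
  residual regional signal remains.
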