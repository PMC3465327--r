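---
title: "Frequency-stratified population structure and association-test calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-stratified population structure and association-test calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratspectrum)
```

## The problem

Population stratification — systematic allele-frequency differences between
subpopulations combined with differential sampling of cases and controls —
creates spurious case-control associations. For common variants (minor
allele frequency, MAF, at least 5%) the correction toolbox is mature:
genomic control, principal-component (PC) adjustment, stratified
Cochran-Mantel-Haenszel (CMH) tests, and mixed models. Rare variants
(MAF at or below 1%) are younger, more geographically clustered, and more
prone to genotyping artifacts, so both their stratification *pattern* and
the behaviour of the standard corrections can differ from the common-variant
case. `stratspectrum` packages the full chain needed to study this:
a structured-cohort simulator, genotype QC, frequency stratification
statistics, PCA and supervised ancestry, and per-variant association scans
summarized by genomic-control inflation.

## The generative model

Regional allele frequencies follow the Balding-Nichols model: for a variant
with ancestral frequency $p$, the frequency in region $r$ is drawn as

$$p_r \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F_{ST}}{F_{ST}},\;
  (1-p)\,\tfrac{1-F_{ST}}{F_{ST}}\right),$$

which has mean $p$ and variance $F_{ST}\,p(1-p)$; $F_{ST}=0$ returns $p$
exactly (no structure). Genotypes of individual $i$ at variant $j$ are
$\mathrm{Binomial}(2, p_{r(i),j})$. Note the frequency-spectrum asymmetry
this implies: the *relative* regional dispersion
$\sqrt{F_{ST}(1-p)/p}$ grows without bound as $p \to 0$, so rare variants
are far more regionally differentiated than common ones at the same
$F_{ST}$ — the qualitative signature observed in real population data.

Ancestral frequencies are drawn uniformly per target stratum:
common $[0.05, 0.5]$, low-frequency $[0.01, 0.05]$, rare $[0.001, 0.01]$.
These intervals emulate a genotyping array's ascertained spectrum (the
lower truncation at $10^{-3}$ stands in for array ascertainment; the
generator makes no attempt to model the full resequencing tail).
A configurable fraction of rare variants is made region-private by zeroing
the regional frequency outside one uniformly chosen region (default 0.2 in
the pipeline; regional sharing analyses of array data show a minority of
rare variants confined to a single region while a few percent reach every
region, so a minority-private spectrum is the realistic default).
Genotyping error perturbs a dosage to an adjacent value ($0 \leftrightarrow
1 \leftrightarrow 2$, direction uniform for heterozygotes) — the simplest
error model that preferentially manufactures spurious rare alleles.
Missingness is i.i.d. per genotype. One global seed fans out to named
per-stage substreams (ancestral draws, regional draws, genotypes, errors,
missingness, case assignment), so any stage can be re-run in isolation and
identical configurations reproduce cohorts bit-for-bit.

Case status is assigned per region. In deterministic-count mode a region of
size $n_r$ with case fraction $f_r$ receives exactly
$\mathrm{round}(f_r n_r)$ cases (chosen uniformly among its members), so a
published design such as 59 cases among 146 and 150 among 273 is
reproduced exactly; Bernoulli mode draws each individual independently.

What the generator deliberately does *not* emulate: linkage disequilibrium
beyond what binomial sampling induces (the pruning stage is exercised with
duplicated-column fixtures instead), haplotype or coalescent structure,
chip ascertainment beyond spectrum truncation, and genotype-intensity-level
artifacts (represented only as missingness plus dosage errors). Passing
tests therefore demonstrate correct behaviour under idealized
exchangeable-variant structure, not under real LD or batch effects.

## Quality control and stratification statistics

QC follows the standard array pipeline: a variant survives if it is typed in
every cohort, has call rate $\ge 0.99$ in every cohort, and its pooled
*control* genotypes are compatible with Hardy-Weinberg proportions at
$p \ge 10^{-8}$. Filters apply in that fixed order and each variant is
counted at its first failing filter, so the QC report partitions the input.
The HWE test is the exact conditional test (enumeration of heterozygote
counts given the minor-allele count): at a threshold as deep as $10^{-8}$
the $\chi^2$ approximation is badly anti-conservative for rare alleles,
which is exactly where the decision matters; a `chisq` fallback is kept
behind a flag for cross-checking. Missing genotypes are excluded from both
numerator and denominator of all frequency computations.

Variants are categorized from control-group MAF: **common** ($\ge 0.05$),
**low-frequency** ($[0.01, 0.05)$), **rare** ($\le 0.01$ with more than two
minor-allele copies), and **others** (at most two copies — singleton and
doubleton signals, the most artifact-prone, are excluded from analysis).
Boundary values go to the commoner category ($0.05$ is common, $0.01$ is
low-frequency). Rare variants are further split at MAF $0.005$ into very
rare and less rare.

Regional structure of a category is summarized three ways:

* **Burden**: per-individual minor-allele count over the category's
  variants (missing dosages contribute 0 — burden is a carrier count and
  imputation would manufacture rare alleles), compared across regions by a
  tie-corrected Kruskal-Wallis test.
* **Sharing**: the number of regions in which each variant has at least one
  minor-allele copy, with the expected proportion of variants present in
  *all* regions under homogeneous allocation computed exactly: $c$ carriers
  allocated without replacement over the pooled sample (multivariate
  hypergeometric over region sizes), $P(\text{every region hit})$ by
  inclusion-exclusion over region subsets (grouped by subset-size through a
  signed polynomial, so 12 regions cost a 4096-term expansion once rather
  than per variant). A Monte-Carlo estimator of the same quantity serves as
  an in-package cross-check.
* **Heterogeneity**: a Pearson $\chi^2$ on the $2 \times R$ allele-count
  table per variant ($R-1$ degrees of freedom; 11 df for 12 regions), with
  an optional permutation p-value obtained by shuffling region labels over
  individuals, add-one corrected: $(b+1)/(n_{\mathrm{perm}}+1)$. Under
  homogeneity the p-values are uniform, so $-2\ln p \sim \chi^2_2$, and the
  overdispersion coefficient

  $$\lambda_r = \frac{\mathrm{median}(-2 \ln p)}{2 \ln 2}$$

  equals 1 under the null. The natural logarithm is used: $-2\ln p$ is the
  quantity that is $\chi^2_2$-distributed. Degenerate tables (a zero
  margin) return $p = 1$ from the single-variant test; the vectorized scan
  returns NA there and such variants are dropped from $\lambda_r$.

Cohort comparability (two control collections drawn from the same
population) is tested by a 1-df Mantel-extension statistic: the CMH
$2 \times 2 \times K$ statistic on cohort-by-allele tables stratified by
region, without continuity correction.

## PCA and supervised ancestry

Before PCA each category is LD-pruned greedily: within a 50-variant window
any retained pair with squared dosage correlation above 0.2 loses its
lower-MAF member (ties: the later position), and the window slides by 5.
The tie-break is a determinism choice; reference pruning tools do not
document theirs.

PCA mean-centers each variant and, under allele-frequency weighting,
divides by $\sqrt{\hat p(1-\hat p)}$ with the posterior-mean estimate
$\hat p = (1 + \sum g)/(2 + 2n)$ — rare variants get large weights but
never infinite ones. Missing dosages are mean-imputed per variant; variants
monomorphic after imputation are dropped with a warning. Scores and
eigenvalues come from the spectral decomposition of the sample-by-sample
covariance (divisor $m$, the variant count, so a single-variant analysis is
well defined), and the proportion of variance explained is each eigenvalue
over the sum of all of them. Eigenvectors are sign-ambiguous, so each
component's sign is fixed by making its largest-magnitude score positive.
No outlier-removal iterations are performed (a deliberate simplification of
the reference implementation's optional behaviour).

Cross-category correlation of structure uses two complements: the squared
Pearson correlation between individual score vectors, and the cumulative
$R^2$ of one component regressed (with intercept) on another analysis' top
ten components — the projection is least-squares, so the cumulative value
can never fall below the best single $R^2$ and is non-decreasing in the
number of components. The disjoint-subset analysis partitions one
category's variants at random into equal subsets and cross-correlates their
PCs, quantifying how much of a structure axis is marker-set noise.

Supervised ancestry fixes per-region allele frequencies from a labelled
reference (pseudocount 0.5 per allele, so no frequency is 0 or 1) and
maximizes, per target individual, the binomial admixture log-likelihood
$\sum_j [g_j \ln(\textstyle\sum_r q_r p_{rj}) + (2-g_j)\ln(1-\sum_r q_r
p_{rj})]$ over the probability simplex by EM. This is a deliberate,
documented simplification of the reference software's block-relaxation
algorithm; correctness is assessed by parameter recovery on simulated
cohorts, not by output-file equality. The log-likelihood is asserted
non-decreasing at every iteration; termination is a total log-likelihood
gain below $10^{-4}$ (the reference software's criterion) or 1,000
iterations with a warning.

One behaviour deserves emphasis. When regions are *not* differentiated
($F_{ST}=0$) the likelihood surface is flat only in the idealized limit of
exactly known, identical frequencies. With frequencies estimated from a
finite reference, sampling noise creates weak but genuine likelihood
structure, and the fully converged maximum-likelihood proportions of an
unstructured individual spread widely over the simplex: across seeds and
reference sizes of 100-500 per region, 40-80% of unstructured individuals
end with a maximum posterior above 0.5, 12-22% at their true region (we
verified the same optima with an independent BFGS optimizer over a logistic
parametrization of the simplex, so this is the likelihood's geometry, not
an EM artifact). Supervised ancestry assignment in weakly structured data
should therefore be read through its *confidence distribution*, not its
argmax: confident assignment of unstructured individuals is an intrinsic
property of the estimator.

## Association scans and the inflation grid

Five testing strategies share a common per-variant interface:

* **Raw** (Armitage trend): $N \hat\rho^2(g, y)$ on the $N$ complete pairs,
  referred to $\chi^2_1$; constant input gives statistic 0.
* **PC-adjusted**: dosage and phenotype residualized on $k$ PCs plus
  intercept; statistic $(N-k-1)\,\hat\rho^2$ of the residuals. With $k=0$
  this equals the trend test up to the factor $N/(N-1)$, asserted exactly
  in the tests. Collinear PC columns are dropped with a warning.
* **CMH**: the $2 \times 2 \times K$ allele-count statistic
  $\left(\sum_k (a_k - E_k)\right)^2 / \sum_k V_k$ with hypergeometric
  variances (denominator $n_k - 1$), no continuity correction; optional
  within-stratum phenotype permutation with add-one correction. With one
  stratum this is the allelic $\chi^2$ scaled by $(n-1)/n$, the standard
  finite-sample relation.
* **Mixed model**: variance components of $y = \mu + u + \varepsilon$,
  $u \sim N(0, \sigma_g^2 K)$, are fitted once under the null by REML —
  after an eigendecomposition of the kinship $K$ the profiled restricted
  likelihood is a 1-D function of $\delta = \sigma_e^2/\sigma_g^2$,
  maximized on $\log\delta \in [\log 10^{-5}, \log 10^{5}]$ to tolerance
  $10^{-6}$. Each variant is then tested by generalized least squares with
  the components held fixed: the rotated, whitened data are fitted by OLS
  and the variant's $F(1, N-2)$ statistic gives the p-value, so an identity
  kinship recovers ordinary regression exactly. The binary phenotype is
  treated as quantitative 0/1, as the reference mixed-model method does;
  when $\hat\sigma_g^2$ hits the zero boundary the scan reduces to ordinary
  regression and says so. The kinship itself is $ZZ'/m$ over a named
  variant set, $Z$ the centered and SD-scaled dosages.
* **Genomic control**: $\lambda_{GC}$ is the median observed statistic over
  the $\chi^2_1$ median ($\approx 0.4549$). Mixed-model p-values are first
  transformed back to $\chi^2_1$ quantiles; all other tests contribute
  their statistics directly.

`scan_and_summarize()` assembles the published-table-shaped grid: one
$\lambda_{GC}$ per method and per MAF category, with the rare category also
split at MAF 0.005. Variants monomorphic in the analyzed sample are
excluded from the medians (association software reports them as NA); the
single-variant functions still return statistic 0 for constant input, per
their documented contract.

## The stratification scenario

The package's confounding benchmark mirrors the published design: a cohort
of 12 regions, with the two scenario regions at their printed sizes
(R11 = 146, R12 = 273) and the remaining ten at 100 individuals each (a
scaled-down stand-in for a few-thousand-control national panel); 20,000
common, 5,000 low-frequency and 20,000 rare variants at $F_{ST} = 0.05$
with 20% region-private rare variants. MAF categories are assigned from the
**full** control set, and the association scans run on the R11/R12 subset
only, with case fractions 59/146 (40.4%) and 150/273 (54.9%). The
full-panel classification step is essential: a variant rare nationally can
be locally common in the two tested regions, and that is precisely the
mechanism by which rare-variant inflation dwarfs common-variant inflation.
A two-region-only design cannot show the effect — under a single $F_{ST}$
the Balding-Nichols *median* noncentrality of rare variants is below the
common-variant one even though the means agree.

At these settings the grid reproduces the expected ordering: raw
$\lambda_{GC}$ of about 1.3 (common), 1.5 (low-frequency) and 2.2 (rare);
CMH on the true strata calibrated for common variants and still inflated
for rare ones; PC adjustment ($k \ge 2$ on the pruned common set) pulling
the common-variant $\lambda$ back to 1. The rare-category median sits on a
discreteness atom (most testable rare variants in a 419-person subset have
one or two carriers, whose trend statistics cluster near 1), which is
itself part of the story: rare-variant test statistics are badly summarized
by $\chi^2_1$ medians, stratification or not.

## Numerical and problem-size choices

Null calibration runs use 2 regions $\times$ 250 samples and $5 \times
10^4$ common variants (the $\lambda_{GC}$ median then has a standard error
of about 0.01, so the $[0.95, 1.05]$ window is a 4-5 sigma check); the
scenario uses the sizes above; ancestry recovery uses $K=3$ regions, 2,000
variants, 100 reference and 100 target individuals per region. Permutation
defaults are 10,000 shuffles with add-one correction where a permutation
p-value is requested. Exact-vs-Monte-Carlo sharing checks use $10^5$
replicates. These sizes are the package's validation conditions; all are
configurable.

Degenerate inputs follow fixed conventions spelled out on each function:
monomorphic variants (HWE p = 1, PCA drop, GRM drop, lambda-median
exclusion), all-missing variants (flagged, excluded), MAF ties at 0.5
(allele2 is the minor allele, for cross-run determinism), p-values of 0 in
$\lambda_r$ (clipped to the smallest positive double with a warning),
degenerate heterogeneity tables (p = 1 with a warning).

## Known limitations

* No LD, haplotypes, or coalescent genealogy; the Balding-Nichols model is
  exchangeable across variants within a stratum.
* The PLINK text dialect does not store allele labels; orientation on read
  is by observed major allele unless a reference-allele table is supplied
  (the binary dialect round-trips exactly, always).
* The mixed model is linear, not logistic; covariates other than PCs are
  out of scope, as are burden/collapsing tests.
* Supervised ancestry is EM over fixed reference frequencies; unsupervised
  model selection over $K$ is out of scope.
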