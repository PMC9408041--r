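---
title: "Partitioned GBLUP with prior-information SNP sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned GBLUP with prior-information SNP sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Genomic prediction estimates an individual's additive genetic merit (its
genomic estimated breeding value, GEBV) from genome-wide SNP genotypes.
The workhorse model, GBLUP, treats every marker effect as a draw from one
normal distribution, which is equivalent to a mixed model with a single
genomic relationship matrix (GRM). That assumption is wasteful when
external biology — QTL catalogues, gene annotations, known causal loci —
says that some markers are likelier to matter than others.

`pgblup` implements a partitioned extension. Let `Z` be the column-standardized
`n x m` genotype matrix and `Z1` the `n x p` sub-matrix for a *prior set* of
p SNPs chosen from external evidence. The phenotype (standardized to mean 0,
variance 1) is modelled as

    y = Z u + Z1 u1 + e,
    u  ~ N(0, sigma2_small / m),
    u1 ~ N(0, sigma2_large / p),
    e  ~ N(0, sigma2_e),

so prior-set SNPs carry both a genome-wide "small" effect and an additional
"large" effect. Collecting genetic values `g_s = Z u`, `g_l = Z1 u1` gives
the equivalent kernel form with two GRMs, `A = Z Z'/m` and `A1 = Z1 Z1'/p`:

    V = A sigma2_small + A1 sigma2_large + I sigma2_e.

Standardization uses the Hardy-Weinberg expected scale,
`(dose - 2f) / sqrt(2 f (1 - f))`, with `f` the allele frequency of the
*training* samples; test genotypes reuse training frequencies so that
training-fitted effects stay applicable. One notational point: the BLUP
equations are sometimes written with the standard deviation symbol where
dimensional consistency requires the variance; this package uses the
variances `sigma2_small`, `sigma2_large` throughout.

### Enrichment

Whether the prior set is worth anything is summarized by the fold of
enrichment,

    fe = (sigma2_large / (sigma2_large + sigma2_small)) / (p / m) + 1,

the share of genetic variance attached to the prior set relative to its
share of markers. Note the additive `+1`: with non-negative components
`fe >= 1` always, and an uninformative prior set sits at 1 rather than 0.
This differs from conventional enrichment ratios but is computed exactly as
defined; treat `fe` as a comparative index, not a ratio of densities.
No standard error is reported for `fe`.

### Estimation and prediction

Variance components are estimated by average-information REML
(`fit_reml()`), with these numerical choices:

* a lone intercept column is always projected out, so unstandardized
  phenotypes remain valid input (for standardized input the projection is
  inert);
* updates use the AI matrix with step-halving, falling back to an EM step
  whenever the AI proposal leaves the feasible region or fails to improve
  the restricted likelihood — the accepted likelihood path is monotone;
* components are floored at `1e-8 * var(y)`; the floor keeps `fe` in its
  valid range and mirrors constrained REML practice;
* initialization is the equal split of `var(y)` across components
  (deterministic; no restarts);
* convergence requires a relative likelihood change below 1e-8 and a
  maximum parameter update below 1e-6, within 100 iterations; standard
  errors come from the inverse AI matrix.

Given fitted components, training-individual genetic values are BLUPs

    g_s_hat = A  sigma2_small V^-1 (y - mu),
    g_l_hat = A1 sigma2_large V^-1 (y - mu),

with `mu` the GLS intercept. Per-SNP effects are backsolved as
`u_hat = Z'(Z Z')^+ g_s_hat` (and likewise for the prior set), using a
Moore-Penrose pseudo-inverse with a relative eigenvalue cutoff of 1e-10:
`Z Z'` is singular whenever columns are dependent, but the BLUP vectors lie
in its range by construction, so the reconstruction identity
`Z u_hat = g_s_hat` holds regardless. Held-out individuals are predicted as

    y_hat = Z_test u_hat + Z1_test u1_hat,

with test matrices standardized at training frequencies. Predictions live
on the standardized-phenotype scale; Pearson correlations with observed
phenotypes — the accuracy metric used throughout — are invariant to that
choice. GBLUP is the exact one-kernel special case, and with the prior set
equal to the whole panel the two components are unidentifiable in direction
while the summed prediction remains well-defined and equal to GBLUP with
the total genetic variance (the enrichment statistic is undefined there and
is reported as absent).

### BayesR baseline

The Bayesian comparator draws each SNP effect from the four-component
mixture `sum_k pi_k N(0, gamma_k sigma2_g)` with fixed
`gamma = (0, 1e-4, 1e-3, 1e-2)`, fitted by Gibbs sampling with a compiled
inner loop. `sigma2_g` is the current sampled genetic variance, updated
every sweep — not a fixed plug-in. The hyperpriors are implementation-defined
(the reference method documents only "defaults"): `pi ~ Dirichlet(1,1,1,1)`
and scaled-inverse-chi-square conditionals for `sigma2_g` and `sigma2_e`
with `nu0 = 4` and prior scale `var(y)/2` each. Chains are bit-reproducible
given a seed. Defaults are 50,000 iterations (20,000 burn-in, thin 10); a
short-chain preset (3,000/1,000/5) serves test suites. One calibration
caveat worth knowing: on null data the null and the `1e-4` components are
nearly indistinguishable at a few hundred samples (the likelihood penalty
scales like `n * gamma_k`), so the posterior mixture weights split between
them even though the implied genetic variance is correctly near zero.

## Quality control and prior-set construction

Per-SNP QC computes all three statistics on the raw matrix and applies them
jointly: a SNP is kept when its Hardy-Weinberg exact-test p-value (two-sided
Wigginton-style enumeration — the test variant is unspecified in common QC
protocols, and the exact test is the default behavior class of standard
tooling), call rate, and minor allele frequency (on non-missing calls) all
clear their thresholds. Two presets reflect common array profiles:
`qc_preset("holstein")` (HWE 1e-4, call rate 95%, MAF 1%) and
`qc_preset("buffalo")` (HWE 1e-5, call rate 97%, MAF 5%). Missing genotypes
are never imputed in storage; they are mean-imputed (standardized value 0)
only at standardization time.

Prior sets can be built from interval evidence with a four-step chain:
keep QTLs strictly shorter than 40 kb; associate genes with a QTL's trait
when the gap between them is at most 50 kb (inclusive, distance 0 for
overlap); keep genes recurrent in at least 4 distinct traits; collect SNPs
within 10 kb of the surviving genes. Coordinates are 0-based half-open
internally; 1-based tables are converted on ingestion (BED-style input via
a flag). "Within X kb" is inclusive and measured from interval boundaries,
not midpoints; gene-trait pairs are deduplicated across overlapping QTLs of
the same trait. These conventions mirror the usual phrasing of such filter
chains; both choices are surfaced as function arguments.

## What the simulator emulates

`simulate_genotypes()` + `simulate_trait()` generate the test bed. The SNP
panel is cut into approximately equal contiguous segments (deterministic
layout, larger segments first); `s` segments are drawn as causal, and the
10 central SNPs of each (offset `floor((len-10)/2)`, a convention for even
lengths) receive additional large effects `N(0, 0.25/k)` on top of
genome-wide small effects `N(0, 0.25/m)`; residuals are `N(0, 0.5)`, so the
expected total heritability is 0.5 split equally between the two classes.
The true fold of enrichment of the causal segments follows in closed form,
`0.5/(p/m) + 1`; at the full design scale (1000 segments of 42-43 SNPs)
this gives 51, 21, 11, 6 and 2 for s = 10, 25, 50, 100 and 500.

Real genotype panels cannot be shipped, so the genotype stand-in draws
per-SNP allele frequencies from Uniform(0.05, 0.45) and builds each
haplotype by a first-order copying chain: with probability `ld_rho`
(default 0.7, giving a realistically reduced effective number of
independent markers) the allele is copied from the adjacent SNP, otherwise
drawn fresh. Adjacent-SNP correlation is close to `ld_rho` (exact for equal
frequencies); the chain runs across the whole SNP axis rather than
restarting at segment boundaries, since real linkage disequilibrium ignores
any arbitrary segment grid. What this stand-in does *not* reproduce:
long-range LD structure, frequency-dependent architecture, ascertainment
bias of commercial arrays, population stratification or family structure.
Passing tests therefore demonstrate correctness of the estimation machinery
and the qualitative method ordering, not performance guarantees on any real
population. Causal segments are redrawn per replicate by default; fixing
them across replicates is possible by reusing a `causal_spec`.

## Cross-validation protocol

`make_folds()` permutes samples and block-splits them so fold sizes differ
by at most one (412 samples -> 83/83/82/82/82; 5024 -> 1005 x 4 + 1004).
Within each fold the training block defines the allele frequencies and the
phenotype standardization; variance components are refit on the training
fold only; test phenotypes are used solely for the final correlation. SNPs
monomorphic within a training fold are dropped for that fold. Fold
correlations are summarized by their mean and, as the dispersion, the
standard deviation across folds (the scale on which such results are
usually reported); the standard error of the mean (`sd/sqrt(k)`) is also
stored. A fold with constant predictions yields an undefined correlation,
which is recorded as missing and excluded from the mean with a warning.
Summaries can be annotated with the heritability-implied ceiling
`sqrt(h2)`, the accuracy the true genetic values themselves would attain —
e.g. 0.707 at h2 = 0.5 and 0.891 at h2 = 0.793.

## Problem sizes used by the test suite

The suite checks parameter recovery at n = 2000, m = 5000 (100 segments, 10
causal, 10 replicates): mean estimated heritability within 0.45-0.55 and
median estimated enrichment within 25% of the closed-form truth of 6. The
method-ordering experiment uses n = 800, m = 2000 with 100 segments —
sparse (s = 10, prior set = causal segments, 10 replicates, expecting the
partitioned model to match or beat GBLUP in at least 8) and polygenic
(s = 50, 4 replicates, all three methods within 0.05), with BayesR on its
short-chain preset. These sizes are the package's reference reduced-scale
designs; enrichment estimates are known to be biased downward at very large
true enrichment because LD leaks heritability into neighboring non-causal
segments, so recovery is asserted at the moderate-enrichment design.

## Known limitations

* GRMs are dense; the implementation targets cohorts up to a few thousand
  individuals, not biobank scale.
* The prior set overlaps the full panel by design (`Z1` is part of `Z`), so
  `A` and `A1` are built from overlapping SNP sets; GRM additivity holds
  only for disjoint partitions and is documented, not "fixed".
* Covariates beyond the intercept, dominance/epistatic kernels,
  single-step pedigree integration and per-animal reliabilities are out of
  scope.
* Pedigree-derived response variables (EBV/DEBV) are consumed as opaque
  phenotype columns; their construction and deregression are upstream of
  this package.
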