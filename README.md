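# pgblup

Genomic prediction with prior-information SNP sets.

`pgblup` is for quantitative geneticists and animal breeders who want to
fold external biological evidence — QTL catalogues, gene annotations, known
causal loci — into genomic prediction, and to ask first whether that
evidence is worth anything. It implements a partitioned genomic best linear
unbiased predictor: the marker panel `Z` (n individuals x m SNPs,
column-standardized) is split so that a prior SNP subset `Z1` (p SNPs)
carries its own variance component on top of the genome-wide one,

    y = Z u + Z1 u1 + e,
    u ~ N(0, sigma2_small / m),  u1 ~ N(0, sigma2_large / p),
    e ~ N(0, sigma2_e),

equivalently a two-kernel mixed model with genomic relationship matrices
`A = ZZ'/m` and `A1 = Z1Z1'/p` and phenotypic covariance
`V = A sigma2_small + A1 sigma2_large + I sigma2_e`. Components are
estimated by average-information REML; the value of the prior set is
summarized by the fold of enrichment

    fe = (sigma2_large / (sigma2_large + sigma2_small)) / (p/m) + 1,

with fe > 1 flagging a heritability-enriched set. Held-out individuals are
predicted from backsolved SNP effects, `u_hat = Z'(ZZ')^+ g_hat`, as
`y_hat = Z_test u_hat + Z1_test u1_hat` (the GEBV). Single-kernel GBLUP and
a four-component mixture-prior BayesR Gibbs sampler are included as
baselines, together with PLINK 1 binary I/O with QC filters (Hardy-Weinberg
exact test, call rate, MAF), a segment-structured trait simulator with
known causal architecture, interval-based prior-set construction from QTL
and gene tables, and a five-fold cross-validation harness.

## Worked example

Simulate a 400-individual, 1000-SNP cohort whose trait draws half its
heritability from 5 causal segments, check the enrichment of the
causal-segment SNP set, and compare cross-validated prediction accuracy:

```r
library(pgblup)

G    <- simulate_genotypes(n = 400, m = 1000, seed = 11)
seg  <- partition_segments(m = 1000, n_segments = 50)
spec <- select_causal(seg, s = 5, seed = 12)
tr   <- simulate_trait(standardize(G), spec, seed = 13)
tr$true_fe
#> [1] 6

z1 <- G$snps$id[spec$z1_snps]
enrichment_report(G, tr$y, z1, mode = "all_individuals")
#> fold of enrichment: 5.2576  (p = 100 of m = 1000 SNPs, h2 = 0.4530)

folds <- make_folds(400, k = 5, seed = 3)
cv_g <- run_cv("gblup",  G, tr$y, folds = folds)
cv_p <- run_cv("pgblup", G, tr$y, z1 = z1, folds = folds)
print(cv_g)
#> gblup cross-validation (5 folds)
#>   fold correlations: 0.4236 0.3724 0.4102 0.4672 0.3196
#>   mean 0.3986  sd 0.0556  se 0.0249
print(cv_p)
#> pgblup cross-validation (5 folds)
#>   fold correlations: 0.4877 0.4084 0.4408 0.4672 0.4555
#>   mean 0.4519  sd 0.0298  se 0.0133
accuracy_gain(cv_p, cv_g)
#> [1] 13.37559
max_achievable_correlation(tr$true_h2)
#> [1] 0.7071068
```

Reading: the causal-segment prior set is strongly enriched (estimated fe
5.26 against a design truth of 6), and feeding it to the partitioned model
lifts the mean predictive correlation from 0.399 to 0.452 (+13.4%), against
a heritability-implied ceiling of 0.707 at h2 = 0.5. With an uninformative
prior set the fitted `sigma2_large` collapses toward zero and pGBLUP falls
back to GBLUP.

A command-line front end wraps the same machinery
(`simulate`, `reml`, `predict`, `bayesr`, `cv`, `make-set`):

```sh
Rscript exec/pgblup simulate --out run/sim --seed 5 --n 500 --m 2000 \
    --n-segments 100 --s 5
Rscript exec/pgblup cv --bfile run/sim --pheno run/sim.pheno \
    --method pgblup --snp-set run/sim.z1.snplist --seed 7 --out run/cv
```

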