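# specBRRR

Heritable low-dimensional modes of multichannel spectral power: Bayesian
reduced-rank regression (BRRR) for band-power brain phenotypes, latent-space
sibling/self "fingerprint" ranking, and a per-variant association scan scored
by the proportion of total variance explained (PTVE).

## Who this is for

Neuro-genetics studies that record multichannel electrophysiology
(MEG/EEG) in family cohorts face a dimensionality problem: the phenotype — a
band power for every sensor and frequency band — has thousands of columns
for a few hundred participants, so neither feature-by-feature heritability
scans nor standard multivariate regression have power. This package fits the
whole phenotype at once through a rank-K factorisation and asks (a) whether
siblings share a low-dimensional spectral structure stable enough to act as
a cortical fingerprint, and (b) whether individual SNPs explain a detectable
share of the phenotype's total variance.

## The model

With `Y` the column-centered N x P band-power matrix, `F` the N x M binary
family indicator, and `g_s` one SNP's (centered) minor-allele counts, the
model is

    Y = (X Psi + Omega) Gamma + E,      X = F   or   X = [F | g_s]

where `Psi` (M' x K) are covariate effects in a K-dimensional latent space,
`Gamma` (K x P) maps the latent space to the features, `Omega` is
latent-space noise, and `E` is residual noise with fixed SD 0.1. Columns of
`Psi` and rows of `Gamma` carry multiplicative-Gamma shrinkage priors
(`tau_k = prod_{l<=k} delta_l`, `delta_1 ~ G(10,1)`,
`delta_{l>1} ~ G(4.1,1)`), which order the components by importance. The
sampler is plain Gibbs: 500 iterations, 250 burn-in, started from a
variance-maximizing SVD initialization.

The association statistic for SNP s is

    PTVE_s = || g_s psi_s Gamma ||_F^2 / || Y_c ||_F^2,

averaged over the retained posterior samples, with the posterior SD as its
standard error. Significance is calibrated against a permutation null
(genotype shuffled across participants, F retained) and summarised with
empirical-Bayes local false discovery rates (point mass at zero plus
half-uniform mixture, fitted by EM); LFDR < 0.05 is "significant",
LFDR < 0.1 "suggestive".

A synthetic-cohort generator (Mendelian sibling genotypes, low-rank familial
phenotypes, planted SNP effects with an exact target PTVE, band-limited raw
signals) makes the entire pipeline testable without protected cohort data.
Genotype QC (call rate, MAF, Hardy-Weinberg exact test, sibling
completeness) and PLINK `.bed/.bim/.fam` round-trip I/O are included. See
`vignettes/specBRRR-methods.Rmd` for the full account of the model,
priors, and design choices.

## Worked example

```r
library(specBRRR)

## 1. Simulate a cohort: 100 sibling-pair families, 100 spectral features,
##    20 SNPs, and one variant planted at PTVE = 0.03 along the leading
##    familial component
co <- simulateCohort(n_families = 100, P = 100, n_snps = 20, seed = 42)
lead <- svd(scale(familyMatrix(co$families) %*% co$truth@psiTrue %*%
                  co$truth@gammaTrue, scale = FALSE), nu = 0, nv = 1)$v[, 1]
g <- alleleCounts(co$genotypes)[, 7]
pheno <- plantSnpEffect(co$phenotype, g, lead, target_ptve = 0.03)

## 2. Familial fit and cross-validated sibling fingerprint
fit <- brrrFit(pheno, familyMatrix(co$families), BRRRConfig(K = 6, seed = 1))
ptve(fit, pheno, familyMatrix(co$families))$mean
#> [1] 0.5126709

familyCrossval(pheno, co$families, BRRRConfig(K = 6, seed = 1),
               n_folds = 10, seed = 1)
#> RankingSummary (sibling): mean rank 1.087 over 200 queries (chance 10.0)

## 3. Association scan with permutation null and LFDR
scan <- snpScan(pheno, co$families, co$genotypes, BRRRConfig(K = 6, seed = 1))
nul  <- permutationNull(pheno, co$families, co$genotypes, n_perm = 60,
                        config = BRRRConfig(K = 6, seed = 1), seed = 2)
scan <- classifyAssociations(
  estimateLfdr(rbind(scan[c("snp", "ptve", "ptve_sd")],
                     nul[c("snp", "ptve", "ptve_sd")]),
               null_offset = mean(nul$ptve)))[1:20, ]
head(scan[order(scan$ptve, decreasing = TRUE), ], 4)
#>         snp        ptve      ptve_sd         lfdr       label
#> 7  snp00007 0.029960085 0.0029481606 1.842082e-19 significant
#> 12 snp00012 0.002362695 0.0007859712 9.944212e-01        null
#> 9  snp00009 0.001747418 0.0006841579 9.983863e-01        null
#> 20 snp00020 0.001631787 0.0007326621 9.988359e-01        null
```

Reading the output: the familial model explains 51% of the phenotype's total
variance (the cohort was generated with a familial share of 0.5); in 10-fold
cross-validation each test participant's sibling is ranked essentially first
among 1 sibling + 18 unrelated candidates (chance would be 10); and the scan
recovers the planted variant at its nominal PTVE of 0.03 with an LFDR of
~2e-19, while all bystander SNPs stay at the null PTVE level (~0.002) with
LFDR near 1.

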