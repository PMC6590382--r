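Package: specBRRR
Title: Bayesian Reduced-Rank Regression for Heritable Spectral Brain Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering heritable low-dimensional modes of
    multichannel spectral power. Implements Bayesian reduced-rank regression
    (BRRR) with multiplicative-Gamma shrinkage priors and family covariates,
    fitted by Gibbs sampling; periodogram band-power phenotyping over
    linearly widening frequency bands; cross-validated latent-space
    "fingerprint" ranking of siblings and of repeated recordings from the
    same participant; and a per-variant association scan scored by the
    proportion of total variance explained (PTVE), calibrated against a
    permutation null and summarised with empirical-Bayes local false
    discovery rates. A synthetic-cohort generator (family-structured
    Mendelian genotypes, low-rank heritable phenotypes, planted variant
    effects, band-limited raw signals) makes the full pipeline testable
    without access to protected cohort data. Genotype quality control and
    PLINK .bed/.bim/.fam input/output are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
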