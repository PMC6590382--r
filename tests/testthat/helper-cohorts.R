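# Small cohort fixtures built in code; kept modest so the suite stays fast.

smallCohort <- function(n_families = 40, P = 30, K_true = 3,
                        familial_share = 0.5, n_snps = 0, seed = 1) {
  simulateCohort(n_families = n_families, P = P, K_true = K_true,
                 familial_share = familial_share, n_snps = n_snps,
                 seed = seed)
}

quickConfig <- function(K = 4, nIter = 150, burnIn = 75, seed = 1) {
  BRRRConfig(K = K, nIter = nIter, burnIn = burnIn, seed = seed)
}

# leading familial component of a synthetic cohort (top right singular
# vector of the centered familial signal)
leadingComponent <- function(cohort) {
  sig <- familyMatrix(cohort$families) %*% cohort$truth@psiTrue %*%
    cohort$truth@gammaTrue
  svd(sweep(sig, 2, colMeans(sig)), nu = 0, nv = 1)$v[, 1]
}

# brute-force familial variance share realized in a cohort
realizedShare <- function(cohort) {
  sig <- familyMatrix(cohort$families) %*% cohort$truth@psiTrue %*%
    cohort$truth@gammaTrue
  sigc <- sweep(sig, 2, colMeans(sig))
  y <- phenoMatrix(cohort$phenotype)
  yc <- sweep(y, 2, colMeans(y))
  sum(sigc^2) / sum(yc^2)
}
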