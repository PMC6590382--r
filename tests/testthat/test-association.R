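test_that("the scan recovers a planted effect and flags monomorphic SNPs", {
  co <- simulateCohort(n_families = 100, P = 100, n_snps = 3, seed = 23)
  g1 <- alleleCounts(co$genotypes)[, 1]
  y2 <- plantSnpEffect(co$phenotype, g1, leadingComponent(co), 0.03)

  counts <- alleleCounts(co$genotypes)
  counts[, 3] <- 0                                   # monomorphic
  counts[1:4, 2] <- NA                               # missing calls imputed
  gt <- GenotypeTable(counts, snpInfo(co$genotypes))
  res <- snpScan(y2, co$families, gt, BRRRConfig(K = 6, seed = 3))

  expect_equal(res$ptve[1], 0.03, tolerance = 0.01 / 0.03)
  expect_true(res$monomorphic[3])
  expect_equal(res$ptve[3], 0)
  expect_gt(res$ptve[1], res$ptve[2])                # planted beats bystander
  expect_true(all(res$ptve_sd[1:2] > 0))
})

test_that("scan results are independent of SNP column order", {
  co <- simulateCohort(n_families = 30, P = 20, n_snps = 3, seed = 24)
  cfg <- quickConfig(K = 3, seed = 5)
  res <- snpScan(co$phenotype, co$families, co$genotypes, cfg)

  counts <- alleleCounts(co$genotypes)[, 3:1]
  info <- snpInfo(co$genotypes)[3:1, ]
  rev_tab <- GenotypeTable(counts, info)
  res_rev <- snpScan(co$phenotype, co$families, rev_tab, cfg)
  expect_equal(res_rev$ptve, rev(res$ptve), tolerance = 1e-12)
  expect_equal(res_rev$ptve_sd, rev(res$ptve_sd), tolerance = 1e-12)
})

test_that("permuted genotypes almost never beat a planted effect", {
  co <- simulateCohort(n_families = 100, P = 40, n_snps = 10, seed = 25)
  g <- alleleCounts(co$genotypes)[, 1]
  y2 <- plantSnpEffect(co$phenotype, g, leadingComponent(co), 0.03)
  cfg <- BRRRConfig(K = 6, nIter = 200, burnIn = 100, seed = 3)

  obs <- specBRRR:::.snpPtve(y2, familyMatrix(co$families),
                             specBRRR:::.imputeSnp(g), cfg, 77)
  nul <- permutationNull(y2, co$families, co$genotypes, n_perm = 200,
                         config = cfg, seed = 9)
  expect_true(all(nul$ptve >= 0))
  expect_gte(mean(nul$ptve < obs["ptve"]), 0.95)
})

test_that("unassociated-SNP PTVEs match the permutation null distribution", {
  ## two-sample Kolmogorov-Smirnov on 200 observed (no effect) vs 200
  ## permuted PTVEs at reduced dimensions, under exchangeable conditions
  ## (no familial phenotype signal; with familial signal the family
  ## structure of a real genotype itself shifts the null upward -- see the
  ## methods vignette)
  co <- simulateCohort(n_families = 60, P = 30, n_snps = 200,
                       familial_share = 0, seed = 26)
  cfg <- BRRRConfig(K = 3, nIter = 150, burnIn = 75, seed = 4)
  obs <- snpScan(co$phenotype, co$families, co$genotypes, cfg)
  nul <- permutationNull(co$phenotype, co$families, co$genotypes,
                         n_perm = 200, config = cfg, seed = 11)
  ks <- suppressWarnings(stats::ks.test(obs$ptve, nul$ptve))
  expect_gt(ks$p.value, 0.01)

  ## planted effects push the observed upper tail above the null's
  g <- alleleCounts(co$genotypes)
  y2 <- co$phenotype
  for (s in 1:5)
    y2 <- plantSnpEffect(y2, g[, s], rnorm(30), 0.02)
  obs2 <- snpScan(y2, co$families,
                  GenotypeTable(g[, 1:40], snpInfo(co$genotypes)[1:40, ]), cfg)
  q_obs <- stats::quantile(obs2$ptve, c(0.95, 0.99))
  q_nul <- stats::quantile(nul$ptve, c(0.95, 0.99))
  expect_true(all(q_obs >= q_nul))
})

test_that("empirical-Bayes LFDR separates nulls from a strong effect", {
  ## all effects exactly zero with tiny SE: everything is null
  rec0 <- data.frame(snp = sprintf("s%03d", 1:100), ptve = 0.01,
                     ptve_sd = 1e-6)
  lf0 <- estimateLfdr(rec0, null_offset = 0.01)
  expect_true(all(lf0$lfdr > 0.99))
  expect_gt(attr(lf0, "mixture")$pi[1], 0.99)

  ## one effect at 10 SE among 500 nulls
  set.seed(27)
  se <- 0.002
  rec <- data.frame(snp = sprintf("s%03d", 1:501),
                    ptve = c(rnorm(500, 0.005, se), 0.005 + 10 * se),
                    ptve_sd = se)
  lf <- estimateLfdr(rec, null_offset = 0.005)
  expect_lt(lf$lfdr[501], 0.05)
  expect_gt(stats::median(lf$lfdr[1:500]), 0.5)

  ## EM objective is non-decreasing
  expect_true(all(diff(attr(lf, "objective")) > -1e-8))

  ## lfdr is non-increasing in ptve at a common SE
  ord <- order(rec$ptve)
  expect_true(all(diff(lf$lfdr[ord]) <= 1e-10))

  expect_error(estimateLfdr(rec0[1:10, ], 0), "at least 50")
})

test_that("LFDR thresholds label significant and suggestive findings", {
  rec <- data.frame(snp = c("a", "b", "c"), ptve = c(0.03, 0.03, 0.01),
                    ptve_sd = 0.003, lfdr = c(0.01, 0.07, 0.5))
  out <- classifyAssociations(rec)
  expect_equal(out$label, c("significant", "suggestive", "null"))
  expect_error(classifyAssociations(rec[, 1:3]), "estimateLfdr")
})

test_that("LFDR-selected discoveries control the false discovery proportion", {
  ## 20 replicates of 300 nulls + 30 real effects; pooled FDP at the 0.05
  ## LFDR threshold stays at or below 0.10
  set.seed(28)
  false_disc <- 0; disc <- 0
  for (r in 1:20) {
    se <- 0.002
    x <- c(rnorm(300, 0, se), abs(rnorm(30, 0.02, 0.005)))
    rec <- data.frame(snp = seq_along(x), ptve = 0.005 + x, ptve_sd = se)
    lf <- estimateLfdr(rec, null_offset = 0.005)
    sel <- which(lf$lfdr < 0.05)
    disc <- disc + length(sel)
    false_disc <- false_disc + sum(sel <= 300)
  }
  expect_gt(disc, 100)               # the effects are actually discoverable
  expect_lte(false_disc / disc, 0.10)
})

test_that("stratification check reports r2, p and the Bonferroni limit", {
  set.seed(29)
  lat <- matrix(rnorm(200 * 6), 200, 6)
  pcs <- matrix(rnorm(200 * 10), 200, 10)
  out <- stratificationCheck(lat, pcs)
  expect_equal(nrow(out), 60L)
  expect_equal(attr(out, "bonferroni_limit"), 0.05 / 60)

  ## a latent component duplicated as a PC gives r2 = 1
  out2 <- stratificationCheck(lat, cbind(lat[, 1], pcs))
  expect_equal(out2$r2[out2$pc == 1 & out2$component == 1], 1, tolerance = 1e-12)

  ## independent Gaussian scores: max r2 below 0.08 in nearly all seeds
  hits <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    max(stratificationCheck(matrix(rnorm(200 * 6), 200, 6),
                            matrix(rnorm(200 * 10), 200, 10))$r2)
  }, 0)
  expect_gte(mean(hits < 0.08), 0.95)

  expect_warning(stratificationCheck(cbind(lat[, 1:2], 1), pcs), "constant")
})

test_that("PTVE is insensitive to K and a noise genotype stays under the null", {
  ## no-signal phenotype: the permutation null is exchangeable with real
  ## unassociated genotypes there (see the null-calibration test above)
  co <- simulateCohort(n_families = 60, P = 30, n_snps = 5,
                       familial_share = 0, seed = 30)
  cfg <- BRRRConfig(K = 3, nIter = 150, burnIn = 75, seed = 4)

  ## single K: deviation is zero by construction
  g <- alleleCounts(co$genotypes)[, 1]
  one <- sensitivityScan(co$phenotype, co$families, g, 3, cfg, seed = 5)
  expect_equal(attr(one, "max_deviation"), 0)

  ## pure-noise genotype: PTVE below the permutation-null 95th percentile
  ## for every K tested
  nul <- permutationNull(co$phenotype, co$families, co$genotypes,
                         n_perm = 40, config = cfg, seed = 12)
  q95 <- stats::quantile(nul$ptve, 0.95)
  ss <- sensitivityScan(co$phenotype, co$families, g, c(2, 4, 6), cfg,
                        seed = 5)
  expect_true(all(ss$ptve < q95 + 1e-3))
  expect_equal(attr(ss, "reference_K"), 6L)
})
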