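test_that("initialization recovers exact low-rank structure and maximizes explained variance", {
  set.seed(1)
  x <- matrix(rnorm(20 * 5), 20, 5)
  psi_t <- matrix(rnorm(5 * 2), 5, 2)
  gam_t <- matrix(rnorm(2 * 8), 2, 8)
  y <- x %*% psi_t %*% gam_t

  ini <- initReducedRank(y, x, 2)
  expect_equal(x %*% ini$Psi0 %*% ini$Gamma0, y, tolerance = 1e-6)

  ## ones column: the single loading row is proportional to the column means
  y2 <- matrix(rnorm(20 * 6), 20, 6) + 5
  ini1 <- initReducedRank(y2, matrix(1, 20, 1), 1)
  cm <- colMeans(y2)
  cosang <- abs(sum(ini1$Gamma0 * cm)) / sqrt(sum(ini1$Gamma0^2) * sum(cm^2))
  expect_equal(cosang, 1, tolerance = 1e-8)

  ## rank-2 initialization attains the brute-force maximum explained variance
  set.seed(2)
  yr <- matrix(rnorm(20 * 8), 20, 8)
  ini2 <- initReducedRank(yr, x, 2)
  fit_full <- x %*% solve(crossprod(x) + diag(1e-8 * sum(diag(crossprod(x))), 5),
                          crossprod(x, yr))
  best2 <- sum(svd(fit_full)$d[1:2]^2)
  expect_equal(sum((x %*% ini2$Psi0 %*% ini2$Gamma0)^2), best2,
               tolerance = 1e-8)

  ## K above the achievable rank is reduced with a warning
  expect_warning(ini3 <- initReducedRank(y, x[, 1, drop = FALSE], 3),
                 "achievable rank")
  expect_equal(ncol(ini3$Psi0), 1L)
})

test_that("the Gibbs sampler is deterministic and keeps nIter - burnIn samples", {
  co <- smallCohort(seed = 2)
  x <- familyMatrix(co$families)
  cfg <- BRRRConfig(K = 2, nIter = 31, burnIn = 30, seed = 7)
  p1 <- brrrFit(co$phenotype, x, cfg)
  expect_equal(dim(p1@psiSamples)[3], 1L)

  cfg2 <- quickConfig(K = 3, nIter = 60, burnIn = 30, seed = 5)
  a <- brrrFit(co$phenotype, x, cfg2)
  b <- brrrFit(co$phenotype, x, cfg2)
  expect_identical(a@psiMean, b@psiMean)
  expect_identical(a@gammaMean, b@gammaMean)
  expect_identical(a@ptveTrace, b@ptveTrace)

  ybad <- phenoMatrix(co$phenotype)
  ybad[1, 1] <- NA
  expect_error(brrrFit(ybad, x, cfg2), "non-finite")
  expect_error(brrrFit(co$phenotype, x, BRRRConfig(K = 90, nIter = 20,
                                                   burnIn = 10)),
               "K must not exceed")
})

test_that("tau is exactly the cumulative product of the sampled delta", {
  co <- smallCohort(seed = 3)
  post <- brrrFit(co$phenotype, familyMatrix(co$families),
                  quickConfig(K = 3, seed = 2))
  expect_identical(post@tauSamples, apply(post@deltaSamples, 2, cumprod))
  expect_true(all(post@tauSamples > 0))
})

test_that("posterior loadings recover the generative latent subspace", {
  co <- simulateCohort(n_families = 50, P = 40, K_true = 3,
                       familial_share = 0.9, seed = 6)
  post <- brrrFit(co$phenotype, familyMatrix(co$families),
                  BRRRConfig(K = 3, seed = 4))
  ang <- specBRRR:::.principalAngles(t(gammaMean(post)),
                                     t(co$truth@gammaTrue))
  expect_lt(max(ang), 5)
})

test_that("PTVE equals the brute-force Frobenius ratio and tracks the generative share", {
  co <- smallCohort(n_families = 5, P = 4, seed = 7)
  x <- familyMatrix(co$families)
  post <- brrrFit(co$phenotype, x, quickConfig(K = 2, nIter = 40, burnIn = 35,
                                               seed = 3))
  pt <- ptve(post, co$phenotype, x)
  yc <- scale(phenoMatrix(co$phenotype), scale = FALSE)
  manual <- vapply(seq_len(5), function(s) {
    fit <- x %*% post@psiSamples[, , s] %*% post@gammaSamples[, , s]
    sum(fit^2) / sum(yc^2)
  }, 0)
  expect_equal(pt$trace, manual, tolerance = 1e-12)
  expect_equal(pt$mean, mean(manual), tolerance = 1e-12)
  expect_error(ptve(post, co$phenotype, x, subset = integer(0)), "empty")

  ## parameter recovery: fitted PTVE close to the realized familial share
  co2 <- simulateCohort(n_families = 100, P = 60, seed = 8)
  x2 <- familyMatrix(co2$families)
  post2 <- brrrFit(co2$phenotype, x2, BRRRConfig(K = 6, seed = 5))
  pt2 <- ptve(post2, co2$phenotype, x2)
  expect_equal(pt2$mean, realizedShare(co2), tolerance = 0.02 / realizedShare(co2))

  ## PTVE grows (weakly) with K on the same data
  post_k2 <- brrrFit(co2$phenotype, x2, BRRRConfig(K = 2, seed = 5))
  pt_k2 <- ptve(post_k2, co2$phenotype, x2)
  expect_gte(pt2$mean, pt_k2$mean - 0.02)
})

test_that("coefficient matrix has rank K and matches hand-computed averages", {
  co <- smallCohort(seed = 9)
  post1 <- brrrFit(co$phenotype, familyMatrix(co$families),
                   quickConfig(K = 1, seed = 2))
  expect_equal(specBRRR:::.numRank(coefficientMatrix(post1)), 1L)

  ## hand-built two-sample posterior: mean of per-sample products
  psiS <- array(c(1, 0, 0, 1), c(2, 1, 2))
  gamS <- array(c(1, 2, 3, 4, 5, 6), c(1, 3, 2))
  delS <- matrix(5, 1, 2)
  cfg <- BRRRConfig(K = 1, nIter = 3, burnIn = 1)
  post2 <- new("BRRRPosterior", psiSamples = psiS, gammaSamples = gamS,
               omegaSamples = array(0, c(2, 1, 2)), deltaSamples = delS,
               tauSamples = delS, psiMean = apply(psiS, c(1, 2), mean),
               gammaMean = apply(gamS, c(1, 2), mean),
               omegaMean = matrix(0, 2, 1), ptveTrace = rep(0.1, 3),
               center = rep(0, 3), yss = 1, config = cfg)
  hand <- (matrix(c(1, 0)) %*% matrix(c(1, 2, 3), 1) +
             matrix(c(0, 1)) %*% matrix(c(4, 5, 6), 1)) / 2
  expect_equal(coefficientMatrix(post2, type = "mean_of_products"), hand)
  expect_equal(coefficientMatrix(post2),
               post2@psiMean %*% post2@gammaMean)
})

test_that("latent embedding inverts the loading map on its row space", {
  ## Gamma = [I 0]: embedding is the first K columns of the centered data
  set.seed(10)
  y <- matrix(rnorm(12 * 6), 12, 6)
  gam <- cbind(diag(2), matrix(0, 2, 4))
  yc <- scale(y, scale = FALSE)
  expect_equal(latentEmbed(y, gam), yc[, 1:2], tolerance = 1e-12,
               ignore_attr = TRUE)

  ## exact inversion: Y = Z Gamma recovers Z (Z column-centered)
  z <- scale(matrix(rnorm(12 * 3), 12, 3), scale = FALSE)
  gam3 <- matrix(rnorm(3 * 8), 3, 8)
  expect_equal(latentEmbed(z %*% gam3, gam3), z, tolerance = 1e-10,
               ignore_attr = TRUE)

  ## pseudo-inverse agrees with the SVD construction
  set.seed(11)
  gam5 <- matrix(rnorm(5 * 12), 5, 12)
  sv <- svd(gam5)
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  y2 <- matrix(rnorm(7 * 12), 7, 12)
  expect_equal(latentEmbed(y2, gam5), scale(y2, scale = FALSE) %*% pinv,
               tolerance = 1e-10, ignore_attr = TRUE)

  ## rank-deficient loadings fall back with a warning
  gdef <- rbind(gam3, gam3[1, ])
  expect_warning(latentEmbed(z %*% gam3, gdef), "rank-deficient")
})

test_that("convergence diagnostic flags unstable traces and accepts long chains", {
  expect_equal(convergenceDiagnostic(rep(0.4, 50))$splitDiff, 0)
  expect_true(convergenceDiagnostic(rep(0.4, 50))$converged)
  expect_false(convergenceDiagnostic(rep(c(0, 1), 25))$converged)

  ## 500- vs 5000-iteration chains agree on PTVE within the tolerance
  co <- simulateCohort(n_families = 30, P = 25, seed = 12)
  x <- familyMatrix(co$families)
  short <- brrrFit(co$phenotype, x, BRRRConfig(K = 3, nIter = 500,
                                               burnIn = 250, seed = 6))
  long <- brrrFit(co$phenotype, x, BRRRConfig(K = 3, nIter = 5000,
                                              burnIn = 250, seed = 7))
  pt_s <- ptve(short, co$phenotype, x)
  pt_l <- ptve(long, co$phenotype, x)
  expect_lt(abs(pt_s$mean - pt_l$mean), 0.005)
  expect_true(convergenceDiagnostic(short)$converged)
})

test_that("posterior mean of beta matches an independent quadrature oracle", {
  ## tiny instance (N=20, P=4, K=1, single covariate): integrate the exact
  ## posterior over (psi, delta) on a grid, with gamma marginalized in
  ## closed form, and compare E[psi * gamma] with the Gibbs estimate
  set.seed(3)
  n <- 20; p <- 4
  x <- rnorm(n)
  gam_t <- c(0.3, -0.2, 0.25, 0.1)
  y <- x %*% t(gam_t) + matrix(rnorm(n * p, sd = 0.1), n, p)
  yc <- scale(y, scale = FALSE)
  s2 <- 0.01
  xx <- sum(x^2)
  xty <- drop(crossprod(x, yc))
  psis <- seq(-3, 3, length.out = 601)
  dels <- seq(0.5, 40, length.out = 400)
  eb <- numeric(p)
  lp <- matrix(NA_real_, length(psis), length(dels))
  for (di in seq_along(dels)) {
    d <- dels[di]
    z2 <- psis^2 * xx
    ## gamma marginalized: y_j ~ N(0, s2 I + (psi x)(psi x)' / d)
    quad <- sum(colSums(yc^2)) - sum(xty^2) * psis^2 / (d * s2 + z2)
    lp[, di] <- -0.5 * p * log(1 + z2 / (d * s2)) - 0.5 * quad / s2 +
      stats::dnorm(psis, 0, 1 / sqrt(d), log = TRUE) +
      stats::dgamma(d, 10, 1, log = TRUE)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  for (di in seq_along(dels)) {
    d <- dels[di]
    v <- 1 / (d + psis^2 * xx / s2)
    ## E[gamma_j | psi, d] = (psi / s2) v xty_j  =>  E[beta_j] adds
    ## sum_psi w * psi^2 * v / s2 * xty_j
    eb <- eb + sum(w[, di] * psis^2 * v / s2) * xty
  }
  post <- brrrFit(yc, matrix(x, ncol = 1),
                  BRRRConfig(K = 1, nIter = 2500, burnIn = 500, seed = 4))
  bet <- drop(coefficientMatrix(post, type = "mean_of_products"))
  expect_lt(max(abs(unname(bet) - eb)), 5e-3)
})
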