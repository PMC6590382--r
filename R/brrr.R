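## Bayesian reduced-rank regression core.
##
## Model: Y_c = (X Psi + Omega) Gamma + E, with Y_c the column-centered
## phenotype, X the covariate matrix (family indicators, optionally a
## genotype column), Psi (M' x K) covariate effects in the latent space,
## Gamma (K x P) the latent-to-feature loadings, Omega (N x K) latent noise
## and E residual noise with fixed SD sigma_e. Shrinkage prior: columns of
## Psi and rows of Gamma are N(0, tau_k^{-1} I), tau_k = prod_{l<=k} delta_l,
## delta_1 ~ Gamma(10, 1), delta_{l>1} ~ Gamma(4.1, 1); Omega columns have
## fixed small SD omega_scale / tau_k. The product beta = Psi Gamma is a
## rank-K regression coefficient matrix.

#' Variance-maximizing initialization of the reduced-rank factors
#'
#' Least-squares fit of the covariates to the phenotype (ridge-stabilized),
#' followed by a rank-K truncated SVD of the fitted values, so that the
#' covariates explain the maximal amount of variance achievable at rank K,
#' with components ordered by decreasing singular value. The phenotype is
#' used as given; pass a column-centered matrix (as [brrrFit()] does
#' internally) for the maximal-variance interpretation.
#'
#' @param Y phenotype (\linkS4class{SpectralPhenotype} or matrix).
#' @param X covariate matrix with N rows.
#' @param K target rank; reduced with a warning when the fitted values do not
#'   support it.
#' @return list with `Psi0` (M x K), `Gamma0` (K x P, orthonormal rows) and
#'   the singular values `d` of the fitted matrix.
#' @export
initReducedRank <- function(Y, X, K) {
  y <- phenoMatrix(Y)
  x <- familyMatrix(X)
  m <- ncol(x)
  xtx <- crossprod(x)
  lam <- 1e-8 * sum(diag(xtx))
  b <- solve(xtx + diag(lam, m), crossprod(x, y))
  fit <- x %*% b
  sv <- svd(fit)
  pos <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  if (K > pos) {
    warning("requested rank ", K, " exceeds achievable rank ", pos,
            "; reduced")
    K <- pos
  }
  v <- sv$v[, seq_len(K), drop = FALSE]
  list(Psi0 = b %*% v, Gamma0 = t(v), d = sv$d[seq_len(K)])
}

#' Fit the reduced-rank regression model by Gibbs sampling
#'
#' Runs `nIter` full-conditional Gibbs updates from the variance-maximizing
#' initialization and retains the post-burn-in draws. The residual SD and the
#' latent-noise scale are fixed (not sampled); the shrinkage multipliers
#' delta are updated through their conjugate Gamma conditionals driven by the
#' Psi and Gamma norms. Deterministic given `config@seed`.
#'
#' @param Y phenotype (\linkS4class{SpectralPhenotype} or N x P matrix);
#'   column-centered internally.
#' @param X covariate matrix (N x M'), e.g. `familyMatrix(fam)` or
#'   `cbind(familyMatrix(fam), g)`.
#' @param config a \linkS4class{BRRRConfig}.
#' @return a \linkS4class{BRRRPosterior}.
#' @export
brrrFit <- function(Y, X, config = BRRRConfig()) {
  y <- phenoMatrix(Y)
  x <- familyMatrix(X)
  if (!all(is.finite(y)) || !all(is.finite(x)))
    stop("non-finite values in Y or X")
  if (nrow(x) != nrow(y)) stop("X and Y row counts differ")
  n <- nrow(y); p <- ncol(y); m <- ncol(x)
  K <- config@K
  if (K > n) stop("K must not exceed the number of participants")
  set.seed(config@seed)
  center <- colMeans(y)
  yc <- sweep(y, 2, center)
  yss <- sum(yc^2)
  if (yss == 0) stop("phenotype has zero variance")
  s2 <- config@sigmaE^2

  ini <- initReducedRank(yc, x, K)
  K <- ncol(ini$Psi0)                      # may have been reduced
  Psi <- ini$Psi0
  Gamma <- ini$Gamma0
  Omega <- matrix(0, n, K)
  delta <- c(config@delta1Shape / config@delta1Rate,
             rep(config@deltaShape / config@deltaRate, K - 1))
  tau <- cumprod(delta)

  xtx <- crossprod(x)
  eg <- eigen(xtx, symmetric = TRUE)
  Q <- eg$vectors
  lamX <- pmax(eg$values, 0)
  Qt <- t(Q)

  n_iter <- config@nIter; burn <- config@burnIn
  n_keep <- n_iter - burn
  psiS <- array(NA_real_, c(m, K, n_keep))
  gamS <- array(NA_real_, c(K, p, n_keep))
  omS <- array(NA_real_, c(n, K, n_keep))
  delS <- matrix(NA_real_, K, n_keep)
  ptve_tr <- numeric(n_iter)

  a1 <- config@delta1Shape; r1 <- config@delta1Rate
  al <- config@deltaShape; rl <- config@deltaRate

  for (it in seq_len(n_iter)) {
    Z <- x %*% Psi + Omega
    ## Gamma | rest: columns are independent K-variate Gaussians sharing the
    ## precision D_tau + Z'Z / s2.
    pg <- diag(tau, K) + crossprod(Z) / s2
    ch <- chol(pg)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, yc) / s2))
    Gamma <- mu + backsolve(ch, matrix(rnorm(K * p), K, p))
    E <- yc - Z %*% Gamma
    ## Psi and Omega, one latent component at a time.
    for (k in seq_len(K)) {
      gk <- Gamma[k, ]
      g2 <- sum(gk^2)
      zk <- Z[, k]
      rk <- drop(E %*% gk) + zk * g2       # R_k Gamma_k' with R_k = E + z_k g_k
      b <- crossprod(x, rk - Omega[, k] * g2) / s2
      dvec <- tau[k] + g2 * lamX / s2
      Psi[, k] <- drop(Q %*% ((Qt %*% b) / dvec + rnorm(m) / sqrt(dvec)))
      xpk <- drop(x %*% Psi[, k])
      prec_o <- (tau[k] / config@omegaScale)^2 + g2 / s2
      mu_o <- (rk - xpk * g2) / (s2 * prec_o)
      Omega[, k] <- mu_o + rnorm(n) / sqrt(prec_o)
      zk_new <- xpk + Omega[, k]
      E <- E - outer(zk_new - zk, gk)
      Z[, k] <- zk_new
    }
    ## delta | rest: conjugate Gamma updates of the multiplicative-Gamma
    ## construction, driven by the Psi-column and Gamma-row norms.
    w <- colSums(Psi^2) + rowSums(Gamma^2)
    for (h in seq_len(K)) {
      tau_wo_h <- cumprod(delta)[h:K] / delta[h]
      shape <- (if (h == 1) a1 else al) + 0.5 * (m + p) * (K - h + 1)
      rate <- (if (h == 1) r1 else rl) + 0.5 * sum(tau_wo_h * w[h:K])
      delta[h] <- rgamma(1, shape, rate)
    }
    tau <- cumprod(delta)
    ptve_tr[it] <- sum((x %*% Psi %*% Gamma)^2) / yss
    if (it > burn) {
      j <- it - burn
      psiS[, , j] <- Psi
      gamS[, , j] <- Gamma
      omS[, , j] <- Omega
      delS[, j] <- delta
    }
  }

  tauS <- apply(delS, 2, cumprod)
  if (K == 1L) tauS <- matrix(tauS, nrow = 1L)
  new("BRRRPosterior",
      psiSamples = psiS, gammaSamples = gamS, omegaSamples = omS,
      deltaSamples = delS, tauSamples = tauS,
      psiMean = apply(psiS, c(1, 2), mean),
      gammaMean = apply(gamS, c(1, 2), mean),
      omegaMean = apply(omS, c(1, 2), mean),
      ptveTrace = ptve_tr, center = center, yss = yss, config = config)
}
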