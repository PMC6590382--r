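## Posterior summaries: PTVE, the rank-K coefficient matrix, the latent
## embedding used for fingerprint ranking, and a chain-convergence check.

#' Proportion of total variance explained by a covariate subset
#'
#' For each retained Gibbs sample s,
#' `PTVE_s = ||X[, subset] Psi_s[subset, ] Gamma_s||_F^2 / ||Y_c||_F^2`.
#' The posterior mean is the reported statistic and the posterior SD serves
#' as its standard error in the association analysis.
#'
#' @param posterior a \linkS4class{BRRRPosterior}.
#' @param Y,X the data the model was fitted to.
#' @param subset covariate (column) indices of X to attribute variance to;
#'   defaults to all covariates.
#' @return list with `mean`, `sd` and the per-sample `trace`.
#' @export
ptve <- function(posterior, Y, X, subset = NULL) {
  x <- familyMatrix(X)
  if (is.null(subset)) subset <- seq_len(ncol(x))
  if (!length(subset)) stop("empty covariate subset")
  if (any(subset < 1 | subset > ncol(x))) stop("subset out of range")
  yc <- .centerCols(phenoMatrix(Y))
  yss <- sum(yc^2)
  xs <- x[, subset, drop = FALSE]
  dp <- dim(posterior@psiSamples)
  dg <- dim(posterior@gammaSamples)
  tr <- vapply(seq_len(dp[3]), function(s) {
    psi_s <- matrix(posterior@psiSamples[, , s], dp[1], dp[2])
    gam_s <- matrix(posterior@gammaSamples[, , s], dg[1], dg[2])
    fit <- xs %*% psi_s[subset, , drop = FALSE] %*% gam_s
    sum(fit^2) / yss
  }, 0)
  list(mean = mean(tr), sd = stats::sd(tr), trace = tr)
}

#' Posterior regression coefficient matrix beta = Psi Gamma
#'
#' The default point estimate is the product of the posterior means,
#' `psiMean %*% gammaMean`, an M' x P matrix whose algebraic rank is at most
#' K (and exactly K for generic posteriors). `type = "mean_of_products"`
#' instead averages the per-sample products `Psi_s Gamma_s`; because the
#' sampled factors fluctuate around the rank-K structure, that average
#' carries a small full-rank Monte-Carlo tail and is useful mainly for
#' posterior-expectation summaries.
#'
#' @param posterior a \linkS4class{BRRRPosterior}.
#' @param type `"product_of_means"` (default) or `"mean_of_products"`.
#' @return M' x P numeric matrix.
#' @export
coefficientMatrix <- function(posterior,
                              type = c("product_of_means",
                                       "mean_of_products")) {
  type <- match.arg(type)
  if (type == "product_of_means")
    return(posterior@psiMean %*% posterior@gammaMean)
  dp <- dim(posterior@psiSamples)
  dg <- dim(posterior@gammaSamples)
  beta <- 0
  for (s in seq_len(dp[3]))
    beta <- beta + matrix(posterior@psiSamples[, , s], dp[1], dp[2]) %*%
      matrix(posterior@gammaSamples[, , s], dg[1], dg[2])
  beta / dp[3]
}

#' Latent-space embedding of phenotype rows
#'
#' Maps participants into the K-dimensional component space through the right
#' pseudo-inverse of Gamma: `Z = Y_c Gamma' (Gamma Gamma')^{-1}`, so that
#' `Z Gamma` is the orthogonal projection of `Y_c` onto the row space of
#' Gamma. Rank-deficient Gamma falls back to a truncated-SVD pseudo-inverse
#' with a warning.
#'
#' @param Y phenotype (\linkS4class{SpectralPhenotype} or matrix).
#' @param Gamma K x P loading matrix.
#' @param center feature means to subtract before embedding; defaults to the
#'   column means of `Y` (pass the training means when embedding test data).
#' @return N x K matrix of latent coordinates.
#' @export
latentEmbed <- function(Y, Gamma, center = NULL) {
  yc <- .centerCols(phenoMatrix(Y), center)
  gg <- tcrossprod(Gamma)
  ev <- eigen(gg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("Gamma is rank-deficient; using truncated-SVD pseudo-inverse")
    sv <- svd(Gamma)
    keep <- sv$d > 1e-10 * sv$d[1]
    pinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    return(yc %*% pinv)
  }
  t(solve(gg, Gamma %*% t(yc)))
}

#' Split-half convergence diagnostic on the PTVE trace
#'
#' Compares the mean PTVE over the first and second halves of the retained
#' trace; a difference above `tol` flags non-convergence.
#'
#' @param posterior a \linkS4class{BRRRPosterior} (or a numeric trace).
#' @param tol flagging tolerance on the split-half mean difference
#'   (default 0.005, i.e. half a percentage point of variance).
#' @return list with the retained `trace`, its `runningMean`, the absolute
#'   `splitDiff` and the logical `converged`.
#' @export
convergenceDiagnostic <- function(posterior, tol = 0.005) {
  if (is(posterior, "BRRRPosterior")) {
    cfg <- posterior@config
    tr <- posterior@ptveTrace[(cfg@burnIn + 1):cfg@nIter]
  } else {
    tr <- as.numeric(posterior)
  }
  if (length(tr) < 2) stop("need at least 2 retained samples")
  half <- floor(length(tr) / 2)
  d <- abs(mean(tr[seq_len(half)]) - mean(tr[(half + 1):length(tr)]))
  list(trace = tr, runningMean = cumsum(tr) / seq_along(tr),
       splitDiff = d, converged = d <= tol)
}
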