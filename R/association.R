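## Per-SNP association scan: one reduced-rank model per variant with
## covariates [F | g_s], scored by the PTVE attributable to the genotype
## column alone; permutation null, empirical-Bayes local false discovery
## rates, a population-stratification check, and a K-sensitivity scan.

# Mean-impute missing calls in one genotype vector.
.imputeSnp <- function(g) {
  miss <- is.na(g)
  if (any(miss)) g[miss] <- mean(g[!miss])
  g
}

# Fit the per-SNP model and return the genotype-attributable PTVE.
# The genotype covariate is mean-centered: the raw count vector's constant
# component lies in the span of the family indicators (rows of F sum to 1),
# which would leave the attribution of that component to the SNP undetermined
# and inflate its PTVE; centering removes the collinearity.
.snpPtve <- function(yc_pheno, fmat, g, config, seed) {
  x <- cbind(fmat, snp = g - mean(g))
  cfg <- config
  cfg@seed <- as.integer(seed)
  post <- brrrFit(yc_pheno, x, cfg)
  pt <- ptve(post, yc_pheno, x, subset = ncol(x))
  c(ptve = pt$mean, ptve_sd = pt$sd)
}

#' Genome-wide per-SNP association scan
#'
#' Fits an independent reduced-rank model for every SNP with covariates
#' `[F | g_s]` (the covariate coefficient matrix gains one row for the
#' genotype) and records the PTVE of the genotype column together with its
#' posterior SD, used downstream as the standard error. Missing genotypes are
#' mean-imputed per SNP; monomorphic SNPs are recorded with PTVE 0 and
#' flagged. Each SNP's chain seed is derived from the configuration seed and
#' the SNP identifier, so results do not depend on column order.
#'
#' @param Y phenotype (\linkS4class{SpectralPhenotype} or matrix).
#' @param families a \linkS4class{FamilyDesign}.
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param config a \linkS4class{BRRRConfig}.
#' @return data.frame with columns `snp`, `chr`, `pos`, `ptve`, `ptve_sd`,
#'   `monomorphic` (the local false discovery rate is added by
#'   [estimateLfdr()]).
#' @export
snpScan <- function(Y, families, genotypes, config = BRRRConfig()) {
  fmat <- familyMatrix(families)
  g <- alleleCounts(genotypes)
  info <- snpInfo(genotypes)
  if (nrow(g) != nrow(fmat)) stop("genotype and family row counts differ")
  d <- ncol(g)
  res <- data.frame(snp = info$id, chr = info$chr, pos = info$pos,
                    ptve = 0, ptve_sd = 0, monomorphic = FALSE,
                    stringsAsFactors = FALSE)
  for (s in seq_len(d)) {
    gs <- .imputeSnp(g[, s])
    if (stats::var(gs) == 0) {
      res$monomorphic[s] <- TRUE
      next
    }
    pt <- .snpPtve(Y, fmat, gs, config,
                   .deriveSeed(config@seed, info$id[s]))
    res$ptve[s] <- pt["ptve"]
    res$ptve_sd[s] <- pt["ptve_sd"]
  }
  res
}

#' Permutation null for the PTVE statistic
#'
#' Each run permutes one genotype vector across participants (the family
#' design is kept in the model), refits the per-SNP model and records the
#' genotype PTVE. SNPs are cycled through in column order.
#'
#' @param Y,families,genotypes,config as in [snpScan()].
#' @param n_perm number of permuted runs (>= 1).
#' @param seed permutation seed.
#' @return data.frame with `run`, `snp`, `ptve`, `ptve_sd`.
#' @export
permutationNull <- function(Y, families, genotypes, n_perm, config = BRRRConfig(),
                            seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  fmat <- familyMatrix(families)
  g <- alleleCounts(genotypes)
  info <- snpInfo(genotypes)
  n <- nrow(g)
  out <- data.frame(run = seq_len(n_perm), snp = NA_character_,
                    ptve = NA_real_, ptve_sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_perm)) {
    s <- (i - 1L) %% ncol(g) + 1L
    gs <- .imputeSnp(g[, s])
    set.seed(.deriveSeed(seed, 50000L + i))
    gs <- gs[sample.int(n)]
    if (stats::var(gs) == 0) {
      out$snp[i] <- info$id[s]; out$ptve[i] <- 0; out$ptve_sd[i] <- 0
      next
    }
    pt <- .snpPtve(Y, fmat, gs, config, .deriveSeed(seed, 60000L + i))
    out$snp[i] <- info$id[s]
    out$ptve[i] <- pt["ptve"]
    out$ptve_sd[i] <- pt["ptve_sd"]
  }
  out
}

#' Empirical-Bayes local false discovery rates for PTVE records
#'
#' Models the null-offset-corrected effects `x_s = ptve_s - null_offset`
#' with standard errors `s_s = ptve_sd_s` as draws from a two-group mixture:
#' a point mass at zero plus half-uniform components `U(0, a_j)` on a
#' geometric grid (a non-negative unimodal effect prior), each convolved
#' with `N(0, s_s^2)`. Mixture proportions are fitted by (penalized) maximum
#' marginal likelihood EM; `lfdr_s` is the posterior probability of the null
#' component. The default penalty up-weights the null as in standard
#' adaptive-shrinkage practice, giving conservative LFDRs.
#'
#' @param records data.frame from [snpScan()] (needs `ptve`, `ptve_sd`).
#' @param null_offset centering constant; PTVE is non-negative, so under the
#'   null the raw values are not centered at zero. Use the mean of the
#'   permutation-null PTVEs ([permutationNull()]).
#' @param penalty Dirichlet pseudo-count on the null proportion (default 10;
#'   1 gives plain maximum likelihood).
#' @param grid_mult geometric spacing of the uniform-component scales.
#' @param tol,max_iter EM convergence controls; non-convergence is an error.
#' @return `records` with an `lfdr` column; mixture diagnostics are attached
#'   as attributes `mixture` (proportions, grid) and `objective` (penalized
#'   log-likelihood trace, non-decreasing).
#' @export
estimateLfdr <- function(records, null_offset, penalty = 10,
                         grid_mult = sqrt(2), tol = 1e-8, max_iter = 5000) {
  if (nrow(records) < 50)
    stop("need at least 50 records to fit the mixture")
  se <- records$ptve_sd
  if (any(se <= 0)) stop("all standard errors must be > 0")
  x <- records$ptve - null_offset
  a_min <- min(se) / 10
  a_max <- max(2 * max(abs(x)), a_min * grid_mult)
  n_grid <- ceiling(log(a_max / a_min) / log(grid_mult))
  a <- a_min * grid_mult^(seq_len(n_grid) - 1)
  n <- length(x)
  ## marginal likelihood matrix: null + each half-uniform component
  L <- matrix(0, n, length(a) + 1)
  L[, 1] <- stats::dnorm(x, 0, se)
  for (j in seq_along(a))
    L[, j + 1] <- (stats::pnorm(x / se) - stats::pnorm((x - a[j]) / se)) / a[j]
  L <- pmax(L, 1e-300)
  k <- ncol(L)
  pi_hat <- rep(1 / k, k)
  obj <- numeric(0)
  pen <- c(penalty, rep(1, k - 1))  # Dirichlet pseudo-counts
  for (it in seq_len(max_iter)) {
    lw <- L %*% pi_hat
    o <- sum(log(lw)) + sum((pen - 1) * log(pmax(pi_hat, 1e-300)))
    obj <- c(obj, o)
    resp <- L * rep(pi_hat, each = n) / as.numeric(lw)
    cnt <- colSums(resp) + pen - 1
    cnt <- pmax(cnt, 0)
    pi_new <- cnt / sum(cnt)
    if (max(abs(pi_new - pi_hat)) < tol) {
      pi_hat <- pi_new
      break
    }
    pi_hat <- pi_new
    if (it == max_iter)
      stop("LFDR mixture EM did not converge after ", max_iter,
           " iterations (last objective change ",
           format(diff(utils::tail(obj, 2))), ")")
  }
  lw <- L %*% pi_hat
  records$lfdr <- pmin(pmax(pi_hat[1] * L[, 1] / as.numeric(lw), 0), 1)
  attr(records, "mixture") <- list(pi = pi_hat, grid = a,
                                   null_offset = null_offset)
  attr(records, "objective") <- obj
  records
}

#' Label association records by LFDR thresholds
#'
#' @param records data.frame with an `lfdr` column.
#' @param significant_lfdr,suggestive_lfdr thresholds (defaults 0.05, 0.1).
#' @return `records` with a `label` column in
#'   \{`significant`, `suggestive`, `null`\}.
#' @export
classifyAssociations <- function(records, significant_lfdr = 0.05,
                                 suggestive_lfdr = 0.1) {
  if (is.null(records$lfdr)) stop("run estimateLfdr() first")
  records$label <- ifelse(records$lfdr < significant_lfdr, "significant",
                          ifelse(records$lfdr < suggestive_lfdr,
                                 "suggestive", "null"))
  records
}

#' Population-stratification check of the latent components
#'
#' Pearson r-squared and p-value for every (ancestry principal component,
#' latent component) pair, with the Bonferroni-corrected significance limit
#' over all tested pairs reported alongside.
#'
#' @param latents N x K matrix of latent component scores.
#' @param pcs N x J matrix of ancestry principal-component scores.
#' @return data.frame with columns `pc`, `component`, `r2`, `p`, `constant`;
#'   the Bonferroni limit `0.05 / (J * K)` is attached as attribute
#'   `bonferroni_limit`.
#' @export
stratificationCheck <- function(latents, pcs) {
  latents <- as.matrix(latents); pcs <- as.matrix(pcs)
  if (nrow(latents) != nrow(pcs)) stop("row counts differ")
  jj <- ncol(pcs); kk <- ncol(latents)
  out <- expand.grid(pc = seq_len(jj), component = seq_len(kk))
  out$r2 <- NA_real_; out$p <- NA_real_; out$constant <- FALSE
  for (r in seq_len(nrow(out))) {
    u <- pcs[, out$pc[r]]; v <- latents[, out$component[r]]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      out$constant[r] <- TRUE
      next
    }
    ct <- stats::cor.test(u, v)
    out$r2[r] <- unname(ct$estimate)^2
    out$p[r] <- ct$p.value
  }
  if (any(out$constant))
    warning("constant column(s): correlation undefined for ",
            sum(out$constant), " pair(s)")
  attr(out, "bonferroni_limit") <- 0.05 / (jj * kk)
  out
}

#' PTVE sensitivity to the latent dimension K
#'
#' Refits the per-SNP model for each K in `K_values` with a common chain
#' seed and reports the genotype PTVE per K plus the maximal absolute
#' deviation from the reference setting (K = 6 when present, otherwise the
#' first value).
#'
#' @param Y,families,config as in [snpScan()].
#' @param g genotype vector (length N; missing calls mean-imputed).
#' @param K_values integer vector of latent dimensions to test.
#' @param seed chain seed shared across the K grid.
#' @return data.frame `(K, ptve, ptve_sd)` with attributes `reference_K` and
#'   `max_deviation`.
#' @export
sensitivityScan <- function(Y, families, g, K_values, config = BRRRConfig(),
                            seed = 1) {
  if (!length(K_values)) stop("K_values must be non-empty")
  fmat <- familyMatrix(families)
  gs <- .imputeSnp(g)
  out <- data.frame(K = as.integer(K_values), ptve = NA_real_,
                    ptve_sd = NA_real_)
  for (i in seq_along(K_values)) {
    cfg <- config
    cfg@K <- as.integer(K_values[i])
    pt <- .snpPtve(Y, fmat, gs, cfg, .deriveSeed(seed, "sensitivity"))
    out$ptve[i] <- pt["ptve"]
    out$ptve_sd[i] <- pt["ptve_sd"]
  }
  ref <- if (6L %in% out$K) which(out$K == 6L)[1] else 1L
  attr(out, "reference_K") <- out$K[ref]
  attr(out, "max_deviation") <- max(abs(out$ptve - out$ptve[ref]))
  out
}
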