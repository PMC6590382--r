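## Synthetic cohort generator: family-structured genotypes by explicit
## Mendelian transmission, low-rank heritable phenotypes, planted variant
## effects and band-limited raw signals. Everything is deterministic given
## the seed argument.

#' Simulate sibling genotypes by Mendelian transmission
#'
#' For every SNP an allele frequency is drawn uniformly from
#' `[maf_low, maf_high]`. For each family, two parental haplotype pairs are
#' drawn under Hardy-Weinberg equilibrium at that frequency, and each sibling
#' inherits one uniformly chosen allele from each parent. Sibling allele
#' sharing (identity-by-descent about 0.5) is therefore emergent rather than
#' imposed through a correlation shortcut.
#'
#' @param n_families number of families (>= 1).
#' @param sibs_per_family siblings per family (>= 2).
#' @param n_snps number of biallelic SNPs.
#' @param maf_low,maf_high minor-allele-frequency range, in (0, 0.5].
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @param missing_rate proportion of calls set to missing (default 0).
#' @return a \linkS4class{GenotypeTable} of minor-allele counts in
#'   \{0, 1, 2\}; rows ordered family-major (`F001_S1`, `F001_S2`, ...).
#' @export
simulateGenotypes <- function(n_families, sibs_per_family, n_snps,
                              maf_low = 0.05, maf_high = 0.5, seed = 1,
                              missing_rate = 0) {
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    stop("minor allele frequencies must satisfy 0 < maf_low <= maf_high <= 0.5")
  if (n_families < 1 || sibs_per_family < 2)
    stop("need n_families >= 1 and sibs_per_family >= 2")
  set.seed(.deriveSeed(seed, "genotypes"))
  maf <- if (maf_low == maf_high) rep(maf_low, n_snps) else
    runif(n_snps, maf_low, maf_high)
  nf <- n_families
  draw_hap <- function() {
    m <- matrix(runif(nf * n_snps), nf, n_snps)
    (m < matrix(maf, nf, n_snps, byrow = TRUE)) + 0
  }
  m1 <- draw_hap(); m2 <- draw_hap()   # maternal haplotypes
  f1 <- draw_hap(); f2 <- draw_hap()   # paternal haplotypes
  n <- nf * sibs_per_family
  g <- matrix(0, n, n_snps)
  for (j in seq_len(sibs_per_family)) {
    cm <- matrix(runif(nf * n_snps) < 0.5, nf, n_snps)
    cf <- matrix(runif(nf * n_snps) < 0.5, nf, n_snps)
    child <- m1 * cm + m2 * (1 - cm) + f1 * cf + f2 * (1 - cf)
    g[seq(j, n, by = sibs_per_family), ] <- child
  }
  rownames(g) <- sprintf("F%03d_S%d", rep(seq_len(nf), each = sibs_per_family),
                         rep(seq_len(sibs_per_family), nf))
  if (missing_rate > 0) {
    drop <- matrix(runif(n * n_snps) < missing_rate, n, n_snps)
    g[drop] <- NA
  }
  GenotypeTable(g)
}

#' Family design matching a simulated genotype table
#'
#' @param n_families,sibs_per_family as in [simulateGenotypes()].
#' @return a \linkS4class{FamilyDesign} with family-major participant order.
#' @export
siblingFamilies <- function(n_families, sibs_per_family = 2) {
  fam <- sprintf("F%03d", rep(seq_len(n_families), each = sibs_per_family))
  names(fam) <- sprintf("%s_S%d", fam, rep(seq_len(sibs_per_family), n_families))
  FamilyDesign(fam)
}

#' Construct generative cohort parameters
#'
#' Draws familial latent coefficients Psi (M x K) and loadings Gamma (K x P)
#' with i.i.d. standard normal entries, then rescales Gamma so that the
#' expected elementwise variance of the familial signal Psi Gamma gives the
#' requested familial variance share against `noise_sd`:
#' `v_signal / (v_signal + noise_sd^2) = familial_share`.
#'
#' @param n_families number of families M.
#' @param P feature dimension.
#' @param K_true generative latent rank.
#' @param familial_share target share of total variance carried by the
#'   familial signal (0 <= share < 1).
#' @param noise_sd residual noise SD (default 0.1, the scale assumed by the
#'   fitted model's fixed residual term).
#' @param seed integer seed.
#' @return a \linkS4class{CohortTruth}.
#' @export
makeCohortTruth <- function(n_families, P, K_true = 6, familial_share = 0.5,
                            noise_sd = 0.1, seed = 1) {
  if (familial_share < 0 || familial_share >= 1)
    stop("familial_share must lie in [0, 1)")
  K_true <- min(K_true, n_families, P)   # latent rank cannot exceed min(M, P)
  set.seed(.deriveSeed(seed, "truth"))
  psi <- matrix(rnorm(n_families * K_true), n_families, K_true)
  gam <- matrix(rnorm(K_true * P), K_true, P)
  if (familial_share > 0 && noise_sd > 0) {
    v_target <- familial_share / (1 - familial_share) * noise_sd^2
    ## calibrate to the realized low-rank draw (assumes equal family sizes):
    ## the centered familial signal gets elementwise mean square v_target
    sig_c <- .centerCols(psi %*% gam)
    gam <- gam * sqrt(v_target / mean(sig_c^2))
  } else if (familial_share == 0) {
    psi[] <- 0
  }
  new("CohortTruth", psiTrue = psi, gammaTrue = gam, snpEffects = list(),
      noiseSd = noise_sd, seed = as.integer(seed))
}

#' Simulate a spectral phenotype from generative truth
#'
#' Generates `Y = F Psi Gamma + E` with i.i.d. Gaussian residuals of SD
#' `noiseSd(truth)`. Fully reproducible from the truth's seed.
#'
#' @param families a \linkS4class{FamilyDesign} (or binary indicator matrix).
#' @param truth a \linkS4class{CohortTruth}.
#' @param condition condition tag for the resulting phenotype.
#' @return a \linkS4class{SpectralPhenotype}.
#' @export
simulatePhenotype <- function(families, truth, condition = "synthetic") {
  f <- familyMatrix(families)
  if (ncol(f) != nrow(truth@psiTrue))
    stop("family count of the design does not match psiTrue rows")
  set.seed(.deriveSeed(truth@seed, "phenotype-noise"))
  n <- nrow(f)
  p <- ncol(truth@gammaTrue)
  y <- f %*% truth@psiTrue %*% truth@gammaTrue +
    matrix(rnorm(n * p, sd = truth@noiseSd), n, p)
  rownames(y) <- rownames(f)
  SpectralPhenotype(y, condition = condition)
}

#' Plant an additive SNP effect with an exact target PTVE
#'
#' Adds `c * (g - mean(g)) %*% direction` to the phenotype, with the scalar c
#' solved in closed form so that the planted term's share of the total
#' (column-centered) variance of the perturbed matrix equals `target_ptve`:
#' `||c (g - mean(g)) d||_F^2 / ||Y'_c||_F^2 = target_ptve`.
#'
#' @param pheno a \linkS4class{SpectralPhenotype} (or matrix).
#' @param g genotype vector of minor-allele counts, length N.
#' @param direction length-P direction of the effect in feature space
#'   (normalized internally).
#' @param target_ptve desired proportion of total variance, in [0, 1).
#' @return the perturbed \linkS4class{SpectralPhenotype}; the scaling
#'   constant is attached as metadata via `attr(phenoMatrix(.), "snp_scale")`.
#' @export
plantSnpEffect <- function(pheno, g, direction, target_ptve) {
  if (target_ptve < 0 || target_ptve >= 1)
    stop("target_ptve must lie in [0, 1)")
  y <- phenoMatrix(pheno)
  if (length(g) != nrow(y)) stop("genotype vector length must equal nrow(Y)")
  if (target_ptve == 0) return(if (is(pheno, "SpectralPhenotype")) pheno
                               else SpectralPhenotype(y))
  u <- g - mean(g)
  if (sum(u^2) == 0) stop("monomorphic genotype: planted effect scale undefined")
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  d <- direction / nd
  yc <- .centerCols(y)
  a <- sum(u^2)                       # ||u d||_F^2 for unit d
  b <- drop(crossprod(u, yc) %*% d)   # <Y_c, u d>
  cc <- sum(yc^2)
  t <- target_ptve
  c_eff <- (t * b + sqrt(t^2 * b^2 + a * (1 - t) * t * cc)) / (a * (1 - t))
  y2 <- y + c_eff * tcrossprod(u, d)
  dimnames(y2) <- dimnames(y)
  attr(y2, "snp_scale") <- c_eff
  out <- SpectralPhenotype(y2, condition = if (is(pheno, "SpectralPhenotype"))
    pheno@condition else "unspecified")
  out
}

#' Simulate band-limited multichannel raw signals
#'
#' Each channel is a sum over bands of FIR band-pass filtered Gaussian white
#' noise, rescaled so the realized variance of each band component equals the
#' requested band-power target. Re-estimating band powers with
#' [spectraMatrix()] recovers the targets up to spectral leakage and
#' periodogram sampling error.
#'
#' @param profile channels x bands matrix of band-power targets (a vector is
#'   treated as a single channel).
#' @param bands two-column (lo, hi) matrix or a \linkS4class{BandScheme}.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param seed integer seed.
#' @return samples x channels numeric matrix with attribute `fs`.
#' @export
simulateRawSignals <- function(profile, bands, duration_s, fs, seed = 1) {
  if (is(bands, "BandScheme")) bands <- bandMatrix(bands)
  bands <- as.matrix(bands)
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  if (ncol(profile) != nrow(bands))
    stop("profile columns must match number of bands")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (max(bands) >= fs / 2)
    stop("band edge at or above the Nyquist frequency ", fs / 2, " Hz")
  n <- round(duration_s * fs)
  n_ch <- nrow(profile)
  x <- matrix(0, n, n_ch)
  colnames(x) <- sprintf("ch%03d", seq_len(n_ch))
  for (ch in seq_len(n_ch)) {
    for (b in seq_len(nrow(bands))) {
      target <- profile[ch, b]
      if (target <= 0) next
      lo <- bands[b, 1]; hi <- bands[b, 2]
      ord <- min(2 * floor((n - 1) / 6),
                 max(256, 2 * ceiling(4 * fs / (hi - lo))))
      set.seed(.deriveSeed(seed, sprintf("raw-%d-%d", ch, b)))
      e <- rnorm(n + 2 * ord)
      h <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
      y <- signal::filtfilt(as.numeric(h), 1, e)
      y <- y[(ord + 1):(ord + n)]
      y <- y - mean(y)
      x[, ch] <- x[, ch] + y * sqrt(target / mean(y^2))
    }
  }
  attr(x, "fs") <- fs
  x
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper producing genotypes, family design, generative truth
#' and the spectral phenotype in one call. Defaults reflect the emulated
#' study: 100 sibling-pair families (about 200 participants), a familial
#' variance share of one half, and residual noise SD 0.1.
#'
#' @param n_families,sibs_per_family family structure.
#' @param P phenotype feature count.
#' @param K_true generative latent rank.
#' @param familial_share familial share of total phenotype variance.
#' @param noise_sd residual noise SD.
#' @param n_snps number of SNPs to simulate (0 skips genotypes).
#' @param maf_low,maf_high allele-frequency range.
#' @param seed integer root seed for all draws.
#' @return list with elements `phenotype`, `families`, `genotypes`
#'   (NULL when `n_snps = 0`) and `truth`.
#' @export
simulateCohort <- function(n_families = 100, sibs_per_family = 2, P = 100,
                           K_true = 6, familial_share = 0.5, noise_sd = 0.1,
                           n_snps = 0, maf_low = 0.05, maf_high = 0.5,
                           seed = 1) {
  fam <- siblingFamilies(n_families, sibs_per_family)
  truth <- makeCohortTruth(n_families, P, K_true, familial_share, noise_sd,
                           seed = .deriveSeed(seed, "cohort-truth"))
  pheno <- simulatePhenotype(fam, truth)
  geno <- NULL
  if (n_snps > 0)
    geno <- simulateGenotypes(n_families, sibs_per_family, n_snps,
                              maf_low, maf_high,
                              seed = .deriveSeed(seed, "cohort-geno"))
  list(phenotype = pheno, families = fam, genotypes = geno, truth = truth)
}
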