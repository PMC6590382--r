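#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers
## ---------------------------------------------------------------------------

#' SpectralPhenotype: participants-by-features band-power matrix
#'
#' Holds the phenotype matrix Y with one row per participant and one column
#' per (channel, band) pair, plus the experimental condition it was derived
#' from. Band powers computed from recordings are non-negative; phenotypes
#' produced by the synthetic generator are real-valued (signal plus Gaussian
#' noise), so non-negativity is not enforced by the class.
#'
#' @slot values numeric matrix, N participants x P features; dimnames carry
#'   participant IDs (rows) and `<channel>_<band>` labels (columns).
#' @slot condition single character tag, e.g. `"eyes_closed"`.
#'
#' @exportClass SpectralPhenotype
setClass("SpectralPhenotype",
         representation(values = "matrix", condition = "character"),
         prototype(values = matrix(numeric(0), 0, 0), condition = "unspecified"))

setValidity("SpectralPhenotype", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (any(!is.finite(v))) return("'values' contains non-finite entries")
  if (length(object@condition) != 1L) return("'condition' must be length 1")
  TRUE
})

#' @rdname SpectralPhenotype-class
#' @param values numeric matrix (participants x features)
#' @param condition condition tag
#' @export
SpectralPhenotype <- function(values, condition = "unspecified") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  new("SpectralPhenotype", values = values, condition = condition)
}

#' FamilyDesign: binary family-membership indicator matrix
#'
#' The design matrix F has one row per participant and one column per family;
#' entry (n, m) is 1 when participant n belongs to family m. Every
#' participant belongs to exactly one family and every family has at least
#' one member.
#'
#' @slot indicator binary numeric matrix N x M.
#' @slot familyIds character vector of length M.
#'
#' @exportClass FamilyDesign
setClass("FamilyDesign",
         representation(indicator = "matrix", familyIds = "character"))

setValidity("FamilyDesign", function(object) {
  f <- object@indicator
  if (!all(f %in% c(0, 1))) return("indicator must be binary")
  if (any(rowSums(f) != 1)) return("each participant must belong to exactly one family")
  if (any(colSums(f) < 1)) return("every family must have at least one member")
  if (length(object@familyIds) != ncol(f)) return("familyIds length must equal ncol(indicator)")
  TRUE
})

#' @rdname FamilyDesign-class
#' @param family vector of family labels, one per participant
#' @export
FamilyDesign <- function(family) {
  family <- as.character(family)
  ids <- unique(family)
  f <- matrix(0, length(family), length(ids),
              dimnames = list(names(family), ids))
  f[cbind(seq_along(family), match(family, ids))] <- 1
  new("FamilyDesign", indicator = f, familyIds = ids)
}

#' GenotypeTable: minor-allele-count matrix with SNP metadata
#'
#' @slot counts numeric matrix N x D with entries in \{0, 1, 2\} or NA
#'   (missing call).
#' @slot snpInfo data.frame with columns `id`, `chr`, `pos`, `a1`, `a2`
#'   (a1 = minor allele, counted allele).
#'
#' @exportClass GenotypeTable
setClass("GenotypeTable",
         representation(counts = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeTable", function(object) {
  g <- object@counts
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok)) return("genotype counts must be 0, 1, 2 or NA")
  if (ncol(g) < 1) return("at least one SNP required")
  if (nrow(object@snpInfo) != ncol(g)) return("snpInfo rows must match SNP count")
  need <- c("id", "chr", "pos", "a1", "a2")
  if (!all(need %in% names(object@snpInfo)))
    return(paste("snpInfo needs columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @rdname GenotypeTable-class
#' @param counts minor-allele count matrix
#' @param snpInfo SNP metadata data.frame (generated when omitted)
#' @export
GenotypeTable <- function(counts, snpInfo = NULL) {
  counts <- as.matrix(counts)
  d <- ncol(counts)
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(id = sprintf("snp%05d", seq_len(d)),
                          chr = rep_len(1:22, d),
                          pos = seq_len(d) * 1000L,
                          a1 = "A", a2 = "B",
                          stringsAsFactors = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- snpInfo$id
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%03d", seq_len(nrow(counts)))
  new("GenotypeTable", counts = counts, snpInfo = snpInfo)
}

#' CohortTruth: generative parameters of a synthetic cohort
#'
#' @slot psiTrue M x K matrix of familial latent coefficients.
#' @slot gammaTrue K x P matrix of latent-to-feature loadings.
#' @slot snpEffects list of planted effects, each
#'   `list(snp =, direction =, size =, target_ptve =)`.
#' @slot noiseSd residual noise standard deviation.
#' @slot seed integer seed that fully determines all draws.
#'
#' @exportClass CohortTruth
setClass("CohortTruth",
         representation(psiTrue = "matrix", gammaTrue = "matrix",
                        snpEffects = "list", noiseSd = "numeric",
                        seed = "integer"))

setValidity("CohortTruth", function(object) {
  k <- ncol(object@psiTrue)
  if (k != nrow(object@gammaTrue)) return("psiTrue / gammaTrue ranks disagree")
  if (k > min(nrow(object@psiTrue), ncol(object@gammaTrue)))
    return("latent rank exceeds min(M, P)")
  if (!all(is.finite(object@gammaTrue))) return("gammaTrue must be finite")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' BandScheme: linearly widening frequency bands with a notch band removed
#'
#' @slot bands numeric matrix (retained bands x 2), columns `lo`, `hi`;
#'   half-open intervals `[lo, hi)`.
#' @slot notchHz power-line frequency whose containing band was dropped.
#' @slot dropped the `(lo, hi)` of the omitted band (length 0 when none).
#' @slot nRetained number of retained bands.
#'
#' @exportClass BandScheme
setClass("BandScheme",
         representation(bands = "matrix", notchHz = "numeric",
                        dropped = "numeric", nRetained = "integer"))

setValidity("BandScheme", function(object) {
  b <- object@bands
  if (ncol(b) != 2) return("bands must have two columns (lo, hi)")
  if (any(b[, 1] >= b[, 2])) return("each band needs lo < hi")
  if (nrow(b) > 1 && any(diff(b[, 1]) <= 0)) return("bands must be ordered")
  if (nrow(b) > 1 && any(b[-nrow(b), 2] > b[-1, 1] + 1e-12))
    return("bands must not overlap")
  if (object@nRetained != nrow(b)) return("nRetained out of sync")
  TRUE
})

#' BRRRConfig: sampler and prior settings for one BRRR fit
#'
#' Defaults follow the analysis configuration: K latent components, 500
#' Gibbs iterations with the first 250 discarded, residual SD fixed at 0.1,
#' latent noise SD fixed at 1e-6 / tau_k, and multiplicative-Gamma shrinkage
#' with delta_1 ~ Gamma(10, 1), delta_{l>1} ~ Gamma(4.1, 1).
#'
#' @slot K integer, number of latent components.
#' @slot nIter,burnIn Gibbs chain length and burn-in.
#' @slot sigmaE fixed residual standard deviation of E.
#' @slot omegaScale multiplier c in the latent-noise SD c / tau_k.
#' @slot delta1Shape,delta1Rate,deltaShape,deltaRate Gamma prior parameters.
#' @slot seed integer root seed of the chain.
#'
#' @exportClass BRRRConfig
setClass("BRRRConfig",
         representation(K = "integer", nIter = "integer", burnIn = "integer",
                        sigmaE = "numeric", omegaScale = "numeric",
                        delta1Shape = "numeric", delta1Rate = "numeric",
                        deltaShape = "numeric", deltaRate = "numeric",
                        seed = "integer"))

setValidity("BRRRConfig", function(object) {
  if (object@K < 1) return("K must be >= 1")
  if (!(object@burnIn > 0 && object@burnIn < object@nIter))
    return("need 0 < burnIn < nIter")
  if (object@sigmaE <= 0 || object@omegaScale <= 0) return("scales must be > 0")
  if (any(c(object@delta1Shape, object@delta1Rate,
            object@deltaShape, object@deltaRate) <= 0))
    return("Gamma prior parameters must be > 0")
  TRUE
})

#' @rdname BRRRConfig-class
#' @param K number of latent components
#' @param nIter,burnIn chain length and burn-in
#' @param sigmaE fixed residual SD
#' @param omegaScale latent-noise SD multiplier
#' @param delta1Shape,delta1Rate,deltaShape,deltaRate shrinkage prior
#' @param seed chain seed
#' @export
BRRRConfig <- function(K = 6, nIter = 500, burnIn = 250, sigmaE = 0.1,
                       omegaScale = 1e-6, delta1Shape = 10, delta1Rate = 1,
                       deltaShape = 4.1, deltaRate = 1, seed = 1) {
  new("BRRRConfig", K = as.integer(K), nIter = as.integer(nIter),
      burnIn = as.integer(burnIn), sigmaE = sigmaE, omegaScale = omegaScale,
      delta1Shape = delta1Shape, delta1Rate = delta1Rate,
      deltaShape = deltaShape, deltaRate = deltaRate, seed = as.integer(seed))
}

#' BRRRPosterior: retained Gibbs samples and posterior means
#'
#' Samples are stored as arrays whose last index runs over the
#' `nIter - burnIn` retained draws. `tauSamples` holds the per-component
#' precisions, computed exactly as cumulative products of the sampled delta.
#'
#' @slot psiSamples M' x K x S array.
#' @slot gammaSamples K x P x S array.
#' @slot omegaSamples N x K x S array.
#' @slot deltaSamples,tauSamples K x S matrices.
#' @slot psiMean,gammaMean,omegaMean posterior means.
#' @slot ptveTrace full-chain PTVE of all covariates, length nIter.
#' @slot center column means subtracted from Y before fitting.
#' @slot yss total sum of squares of the centered Y (PTVE denominator).
#' @slot config the \linkS4class{BRRRConfig} used.
#'
#' @exportClass BRRRPosterior
setClass("BRRRPosterior",
         representation(psiSamples = "array", gammaSamples = "array",
                        omegaSamples = "array", deltaSamples = "matrix",
                        tauSamples = "matrix", psiMean = "matrix",
                        gammaMean = "matrix", omegaMean = "matrix",
                        ptveTrace = "numeric", center = "numeric",
                        yss = "numeric", config = "BRRRConfig"))

setValidity("BRRRPosterior", function(object) {
  s <- dim(object@psiSamples)[3]
  cfg <- object@config
  if (s != cfg@nIter - cfg@burnIn)
    return("retained sample count must equal nIter - burnIn")
  if (any(object@tauSamples <= 0)) return("tau must be positive")
  tau2 <- apply(object@deltaSamples, 2, cumprod)
  if (cfg@K == 1L) tau2 <- matrix(tau2, nrow = 1L)
  if (max(abs(tau2 - object@tauSamples)) > 0)
    return("tau must be the cumulative product of delta")
  TRUE
})

#' RankingSummary: latent-space identification ranks
#'
#' @slot meanRank mean rank over all queries (1 = perfect; with the default
#'   candidate set of 1 related + 18 unrelated, 10 = chance).
#' @slot ranks per-query ranks (midranks on ties, averaged over candidate
#'   resamplings).
#' @slot nCandidates candidate-set size (default 19).
#' @slot segmentLengthS seconds of data behind each embedding (NA when the
#'   phenotype was supplied directly).
#' @slot condition condition tag of the ranking experiment.
#' @slot K latent dimension used (NA for the full-data baseline).
#'
#' @exportClass RankingSummary
setClass("RankingSummary",
         representation(meanRank = "numeric", ranks = "numeric",
                        nCandidates = "integer", segmentLengthS = "numeric",
                        condition = "character", K = "integer"))

setValidity("RankingSummary", function(object) {
  if (length(object@ranks) &&
      (min(object@ranks) < 1 || max(object@ranks) > object@nCandidates))
    return("ranks must lie in [1, nCandidates]")
  if (length(object@ranks) &&
      (object@meanRank < 1 || object@meanRank > object@nCandidates))
    return("meanRank must lie in [1, nCandidates]")
  TRUE
})

RankingSummary <- function(ranks, nCandidates, segmentLengthS = NA_real_,
                           condition = "unspecified", K = NA_integer_) {
  new("RankingSummary", meanRank = mean(ranks), ranks = as.numeric(ranks),
      nCandidates = as.integer(nCandidates),
      segmentLengthS = as.numeric(segmentLengthS),
      condition = condition, K = as.integer(K))
}

#' QCThresholds: genotype quality-control cutoffs
#'
#' Defaults: markers kept when call rate > 0.98, individuals when call rate
#' > 0.95, markers when minor allele frequency > 0.05 and Hardy-Weinberg
#' exact p > 1e-4.
#'
#' @slot markerCallMin,individualCallMin,mafMin,hwePMin cutoffs in (0, 1).
#'
#' @exportClass QCThresholds
setClass("QCThresholds",
         representation(markerCallMin = "numeric", individualCallMin = "numeric",
                        mafMin = "numeric", hwePMin = "numeric"))

setValidity("QCThresholds", function(object) {
  v <- c(object@markerCallMin, object@individualCallMin,
         object@mafMin, object@hwePMin)
  if (any(v <= 0 | v >= 1)) return("thresholds must lie in (0, 1)")
  TRUE
})

#' @rdname QCThresholds-class
#' @param markerCallMin,individualCallMin minimum call rates
#' @param mafMin minimum minor allele frequency
#' @param hwePMin minimum Hardy-Weinberg exact-test p-value
#' @export
QCThresholds <- function(markerCallMin = 0.98, individualCallMin = 0.95,
                         mafMin = 0.05, hwePMin = 1e-4) {
  new("QCThresholds", markerCallMin = markerCallMin,
      individualCallMin = individualCallMin, mafMin = mafMin,
      hwePMin = hwePMin)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SpectralPhenotype", function(object) {
  cat(sprintf("SpectralPhenotype: %d participants x %d features (condition: %s)\n",
              nrow(object@values), ncol(object@values), object@condition))
})

setMethod("show", "FamilyDesign", function(object) {
  cat(sprintf("FamilyDesign: %d participants in %d families\n",
              nrow(object@indicator), ncol(object@indicator)))
})

setMethod("show", "GenotypeTable", function(object) {
  nmiss <- sum(is.na(object@counts))
  cat(sprintf("GenotypeTable: %d participants x %d SNPs (%d missing calls)\n",
              nrow(object@counts), ncol(object@counts), nmiss))
})

setMethod("show", "BandScheme", function(object) {
  cat(sprintf("BandScheme: %d retained bands, %.3g-%.3g Hz",
              object@nRetained, min(object@bands), max(object@bands)))
  if (length(object@dropped))
    cat(sprintf("; [%.3g, %.3g) dropped around %g Hz",
                object@dropped[1], object@dropped[2], object@notchHz))
  cat("\n")
})

setMethod("show", "BRRRConfig", function(object) {
  cat(sprintf("BRRRConfig: K=%d, %d iterations (%d burn-in), sigma_e=%g, seed=%d\n",
              object@K, object@nIter, object@burnIn, object@sigmaE, object@seed))
})

setMethod("show", "BRRRPosterior", function(object) {
  d <- dim(object@psiSamples)
  cat(sprintf("BRRRPosterior: %d retained samples, %d covariates, K=%d, P=%d\n",
              d[3], d[1], d[2], dim(object@gammaSamples)[2]))
})

setMethod("show", "RankingSummary", function(object) {
  cat(sprintf("RankingSummary (%s): mean rank %.3f over %d queries (chance %.1f)\n",
              object@condition, object@meanRank, length(object@ranks),
              (object@nCandidates + 1) / 2))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' @describeIn SpectralPhenotype-class extract the N x P phenotype matrix
#' @param x object
#' @export
setGeneric("phenoMatrix", function(x) standardGeneric("phenoMatrix"))

#' @export
setMethod("phenoMatrix", "SpectralPhenotype", function(x) x@values)

#' @export
setMethod("phenoMatrix", "matrix", function(x) x)

#' @describeIn FamilyDesign-class extract the N x M indicator matrix
#' @param x object
#' @export
setGeneric("familyMatrix", function(x) standardGeneric("familyMatrix"))

#' @export
setMethod("familyMatrix", "FamilyDesign", function(x) x@indicator)

#' @export
setMethod("familyMatrix", "matrix", function(x) x)

#' @describeIn FamilyDesign-class family identifiers
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @export
setMethod("familyIds", "FamilyDesign", function(x) x@familyIds)

#' @describeIn GenotypeTable-class extract the N x D count matrix
#' @param x object
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @export
setMethod("alleleCounts", "GenotypeTable", function(x) x@counts)

#' @describeIn GenotypeTable-class SNP metadata
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setMethod("snpInfo", "GenotypeTable", function(x) x@snpInfo)

#' @describeIn BandScheme-class retained (lo, hi) band matrix
#' @param x object
#' @export
setGeneric("bandMatrix", function(x) standardGeneric("bandMatrix"))

#' @export
setMethod("bandMatrix", "BandScheme", function(x) x@bands)

#' @describeIn BRRRPosterior-class posterior mean of the latent-to-feature
#'   loading matrix Gamma (K x P)
#' @param x object
#' @export
setGeneric("gammaMean", function(x) standardGeneric("gammaMean"))

#' @export
setMethod("gammaMean", "BRRRPosterior", function(x) x@gammaMean)

#' @describeIn BRRRPosterior-class posterior mean of the covariate
#'   coefficient matrix Psi (M' x K)
#' @export
setGeneric("psiMean", function(x) standardGeneric("psiMean"))

#' @export
setMethod("psiMean", "BRRRPosterior", function(x) x@psiMean)

#' @describeIn BRRRPosterior-class full-chain PTVE trace (all covariates)
#' @export
setGeneric("ptveTrace", function(x) standardGeneric("ptveTrace"))

#' @export
setMethod("ptveTrace", "BRRRPosterior", function(x) x@ptveTrace)

#' @describeIn RankingSummary-class mean identification rank
#' @param x object
#' @export
setGeneric("meanRank", function(x) standardGeneric("meanRank"))

#' @export
setMethod("meanRank", "RankingSummary", function(x) x@meanRank)

#' @describeIn RankingSummary-class per-query ranks
#' @export
setGeneric("queryRanks", function(x) standardGeneric("queryRanks"))

#' @export
setMethod("queryRanks", "RankingSummary", function(x) x@ranks)
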