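## Genotype quality control, Hardy-Weinberg exact test, PLINK .bed/.bim/.fam
## round-trip I/O and TSV import/export.

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on the heterozygote count given the minor-allele
#' count (mid-p off): the p-value is the total probability of heterozygote
#' counts no more likely than the observed one. Probabilities are evaluated
#' through the standard stable recurrence over the feasible heterozygote
#' range.
#'
#' @param n_het number of heterozygotes.
#' @param n_hom_minor,n_hom_major homozygote counts.
#' @return two-sided exact p-value.
#' @export
hweExactTest <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0) return(1)
  na <- 2 * n_hom_minor + n_het          # minor allele count
  if (na > n) stop("minor homozygote/het counts exceed the minor allele count")
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - na * (2 * n - na) / (2 * n)))
  probs[mid] <- 1
  if (mid < length(hets)) {
    for (i in mid:(length(hets) - 1)) {
      h <- hets[i]
      aa <- (na - h) / 2
      bb <- n - aa - h
      probs[i + 1] <- probs[i] * 4 * aa * bb / ((h + 1) * (h + 2))
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      h <- hets[i]
      aa <- (na - h) / 2
      bb <- n - aa - h
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (aa + 1) * (bb + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_het)
  if (!length(obs)) stop("observed heterozygote count infeasible")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

# Call rate, MAF and founder HWE p for each marker.
.markerStats <- function(counts, founder_rows) {
  d <- ncol(counts)
  call <- colMeans(!is.na(counts))
  p_minor <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(p_minor, 1 - p_minor)
  hwe <- vapply(seq_len(d), function(s) {
    g <- counts[founder_rows, s]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    ## test on the minor allele within the founder subset
    if (mean(g) / 2 > 0.5) g <- 2 - g
    hweExactTest(sum(g == 1), sum(g == 2), sum(g == 0))
  }, 0)
  data.frame(call = call, maf = maf, hwe = hwe)
}

#' Genotype quality control
#'
#' Applies the filter chain in order: (1) drop markers with call rate at or
#' below `markerCallMin`; (2) drop individuals with call rate at or below
#' `individualCallMin`; (3) drop markers with MAF at or below `mafMin` or
#' Hardy-Weinberg exact p at or below `hwePMin` (HWE evaluated on one
#' individual per family when a family design is supplied); (4) drop
#' individuals left without any passing sibling. The chain is idempotent.
#'
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param thresholds a \linkS4class{QCThresholds}.
#' @param families optional \linkS4class{FamilyDesign}; enables the founder
#'   HWE subset and the sibling-completeness step.
#' @return list with the filtered `genotypes`, the filtered `families` (or
#'   NULL), and a `report` data.frame of per-step removal counts.
#' @export
genotypeQC <- function(genotypes, thresholds = QCThresholds(),
                       families = NULL) {
  g <- alleleCounts(genotypes)
  info <- snpInfo(genotypes)
  fam_of <- if (!is.null(families))
    apply(familyMatrix(families), 1, which.max) else seq_len(nrow(g))
  report <- data.frame(step = character(0), markers_removed = integer(0),
                       individuals_removed = integer(0))
  log_step <- function(step, mk, id) {
    report <<- rbind(report, data.frame(step = step, markers_removed = mk,
                                        individuals_removed = id))
  }
  founders <- function() which(!duplicated(fam_of))

  ## 1. marker call rate
  call_m <- colMeans(!is.na(g))
  keep_m <- call_m > thresholds@markerCallMin
  log_step("marker_call_rate", sum(!keep_m), 0L)
  g <- g[, keep_m, drop = FALSE]; info <- info[keep_m, , drop = FALSE]
  if (!ncol(g)) stop("all markers removed by the marker call-rate filter")

  ## 2. individual call rate
  call_i <- rowMeans(!is.na(g))
  keep_i <- call_i > thresholds@individualCallMin
  log_step("individual_call_rate", 0L, sum(!keep_i))
  g <- g[keep_i, , drop = FALSE]; fam_of <- fam_of[keep_i]

  ## 3. MAF and HWE
  st <- .markerStats(g, founders())
  keep_m <- st$maf > thresholds@mafMin & st$hwe > thresholds@hwePMin
  log_step("maf_hwe", sum(!keep_m), 0L)
  g <- g[, keep_m, drop = FALSE]; info <- info[keep_m, , drop = FALSE]
  if (!ncol(g)) stop("all markers removed by the MAF/HWE filter")

  ## 4. sibling completeness
  if (!is.null(families)) {
    keep_i <- ave(fam_of, fam_of, FUN = length) >= 2
    log_step("sibling_completeness", 0L, sum(!keep_i))
    g <- g[keep_i, , drop = FALSE]; fam_of <- fam_of[keep_i]
  }

  fam_out <- NULL
  if (!is.null(families)) {
    lab <- familyIds(families)[fam_of]
    names(lab) <- rownames(g)
    fam_out <- FamilyDesign(lab)
  }
  list(genotypes = GenotypeTable(g, info), families = fam_out,
       report = report)
}

## ---------------------------------------------------------------------------
## PLINK .bed/.bim/.fam (v1, SNP-major)
## ---------------------------------------------------------------------------

# two-bit codes (LSB first within a byte): 00 = hom A1 (2 minor alleles),
# 01 = missing, 10 = het, 11 = hom A2 (0 minor alleles)
.bedCodeOf <- c(`2` = 0L, `1` = 2L, `0` = 3L)   # genotype count -> code
.bedCountOf <- c(2, NA, 1, 0)                   # code + 1      -> count

#' Write genotypes as PLINK .bed/.bim/.fam
#'
#' SNP-major PLINK v1 binary format; the first (counted) allele A1 is the
#' minor allele. The round trip through [readPlink()] is bit-exact for
#' \{0, 1, 2, missing\}.
#'
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param prefix output path prefix (writes `<prefix>.bed/.bim/.fam`).
#' @param families optional \linkS4class{FamilyDesign} supplying family IDs
#'   for the .fam file.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(genotypes, prefix, families = NULL) {
  g <- alleleCounts(genotypes)
  info <- snpInfo(genotypes)
  n <- nrow(g); d <- ncol(g)
  ids <- rownames(g)
  fid <- if (!is.null(families))
    familyIds(families)[apply(familyMatrix(families), 1, which.max)] else ids
  utils::write.table(
    data.frame(fid, ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(info$chr, info$id, 0L, info$pos, info$a1, info$a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  codes <- matrix(1L, n, d)                       # default: missing (01)
  obs <- !is.na(g)
  codes[obs] <- .bedCodeOf[as.character(g[obs])]
  bpl <- ceiling(n / 4)                           # bytes per SNP block
  pad <- bpl * 4 - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, d))
  shift <- rep(c(1L, 4L, 16L, 64L), bpl)
  bytes <- vapply(seq_len(d), function(s) {
    v <- codes[, s] * shift
    as.integer(colSums(matrix(v, 4, bpl)))
  }, integer(bpl))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read genotypes from PLINK .bed/.bim/.fam
#'
#' @param prefix path prefix of the fileset.
#' @return list with the \linkS4class{GenotypeTable} and a
#'   \linkS4class{FamilyDesign} built from the .fam family IDs (families of
#'   size one are retained as singletons).
#' @export
readPlink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); d <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * d + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic-byte mismatch)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  bpl <- ceiling(n / 4)
  if (length(body) != bpl * d)
    stop(".bed size (", length(body), " data bytes) does not match ",
         n, " samples x ", d, " SNPs from .fam/.bim")
  ## decode all bytes at once through a 256 x 4 lookup of two-bit fields
  lut <- cbind(bitwAnd(0:255, 3L), bitwAnd(bitwShiftR(0:255, 2L), 3L),
               bitwAnd(bitwShiftR(0:255, 4L), 3L), bitwShiftR(0:255, 6L))
  codes <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = bpl * 4)
  counts <- matrix(.bedCountOf[codes[seq_len(n), , drop = FALSE] + 1L], n, d)
  rownames(counts) <- fam[[2]]
  info <- data.frame(id = bim[[2]], chr = bim[[1]], pos = bim[[4]],
                     a1 = as.character(bim[[5]]), a2 = as.character(bim[[6]]),
                     stringsAsFactors = FALSE)
  colnames(counts) <- info$id
  fam_lab <- as.character(fam[[1]])
  names(fam_lab) <- fam[[2]]
  list(genotypes = GenotypeTable(counts, info),
       families = FamilyDesign(fam_lab))
}

## ---------------------------------------------------------------------------
## TSV import/export
## ---------------------------------------------------------------------------

#' Write a spectral phenotype (with family labels) as TSV
#'
#' Layout: header `participant, family, condition, <chan>_<band>, ...`,
#' tab-separated, `NA` for missing.
#'
#' @param pheno a \linkS4class{SpectralPhenotype}.
#' @param families a \linkS4class{FamilyDesign} in the same row order.
#' @param file output path.
#' @export
writePhenotypeTSV <- function(pheno, families, file) {
  y <- phenoMatrix(pheno)
  fam <- familyIds(families)[apply(familyMatrix(families), 1, which.max)]
  df <- data.frame(participant = rownames(y), family = fam,
                   condition = pheno@condition, y, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(file)
}

#' Read a spectral phenotype TSV written by [writePhenotypeTSV()]
#'
#' @param file input path.
#' @return list with `phenotype` and `families`.
#' @export
readPhenotypeTSV <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  y <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(y) <- df$participant
  fam <- df$family
  names(fam) <- df$participant
  list(phenotype = SpectralPhenotype(y, condition = df$condition[1]),
       families = FamilyDesign(fam))
}

#' Write genotypes as a TSV fallback (SNP rows, participant columns)
#'
#' @param genotypes a \linkS4class{GenotypeTable}.
#' @param file output path.
#' @export
writeGenotypeTSV <- function(genotypes, file) {
  g <- alleleCounts(genotypes)
  df <- cbind(snpInfo(genotypes), as.data.frame(t(g), check.names = FALSE))
  utils::write.table(df, file, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(file)
}

#' Read a genotype TSV written by [writeGenotypeTSV()]
#'
#' @param file input path.
#' @return a \linkS4class{GenotypeTable}.
#' @export
readGenotypeTSV <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- df[, c("id", "chr", "pos", "a1", "a2")]
  g <- t(as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE]))
  storage.mode(g) <- "double"
  colnames(g) <- meta$id
  GenotypeTable(g, meta)
}

#' Write association-scan records as TSV
#'
#' @param records data.frame from [snpScan()] / [estimateLfdr()] /
#'   [classifyAssociations()].
#' @param file output path.
#' @export
writeAssociationTSV <- function(records, file) {
  utils::write.table(records, file, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(file)
}
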