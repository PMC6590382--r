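## Latent-space "fingerprint" ranking: how close is a participant's sibling
## (or the participant's own data from another time window) in the
## K-dimensional component space, relative to a set of unrelated candidates?

#' Rank the related candidate by L1 distance
#'
#' Candidates are sorted by ascending L1 distance to the query; the returned
#' value is the position of the related candidate, with midranks on exact
#' ties. Rank 1 is perfect; with 19 candidates, 10 is chance level.
#'
#' @param query numeric K-vector (latent coordinates of the query).
#' @param related_index row index of the related candidate.
#' @param candidates candidates x K numeric matrix.
#' @return the (mid)rank of the related candidate.
#' @export
rankByL1 <- function(query, related_index, candidates) {
  candidates <- as.matrix(candidates)
  if (nrow(candidates) < 2) stop("need at least 2 candidates")
  if (related_index < 1 || related_index > nrow(candidates))
    stop("related_index out of range")
  d <- rowSums(abs(sweep(candidates, 2, query)))
  if (any(is.na(d))) stop("non-finite coordinates in ranking")
  rank(d, ties.method = "average")[related_index]
}

# Shared ranking engine: for each query row, rank the related row against
# n_unrelated others sampled (seeded) from an exclusion-aware pool, repeated
# n_repeats times and averaged.
.rankQueries <- function(emb_query, emb_pool, related_of, exclude_of,
                         n_unrelated, n_repeats, seed) {
  n_q <- nrow(emb_query)
  ranks <- numeric(n_q)
  for (i in seq_len(n_q)) {
    pool <- setdiff(seq_len(nrow(emb_pool)), exclude_of[[i]])
    if (length(pool) < n_unrelated)
      stop("not enough unrelated candidates (have ", length(pool),
           ", need ", n_unrelated, ")")
    set.seed(.deriveSeed(seed, i))
    r <- vapply(seq_len(n_repeats), function(rep) {
      cand <- c(related_of[i], sample(pool, n_unrelated))
      rankByL1(emb_query[i, ], 1L, emb_pool[cand, , drop = FALSE])
    }, 0)
    ranks[i] <- mean(r)
  }
  ranks
}

#' Cross-validated sibling ranking in the familial latent space
#'
#' Families are assigned to folds as whole units. Per fold, the model is
#' fitted on the training families only; all participants are then embedded
#' with the fitted loadings (centering on the training feature means), and
#' each test participant who has a sibling queries for that sibling among
#' `n_unrelated` candidates sampled from outside the query's family. The
#' candidate set is resampled `n_repeats` times and ranks averaged.
#'
#' @param Y phenotype (\linkS4class{SpectralPhenotype} or matrix).
#' @param families a \linkS4class{FamilyDesign}.
#' @param config a \linkS4class{BRRRConfig}.
#' @param n_folds number of cross-validation folds (default 10).
#' @param n_unrelated unrelated candidates per query (default 18, so 19
#'   candidates in total and a chance-level mean rank of 10).
#' @param n_repeats candidate-set resamplings per query (default 20).
#' @param seed seed for fold assignment and candidate sampling.
#' @return a \linkS4class{RankingSummary} with one rank per query.
#' @export
familyCrossval <- function(Y, families, config = BRRRConfig(), n_folds = 10,
                           n_unrelated = 18, n_repeats = 20, seed = 1) {
  y <- phenoMatrix(Y)
  f <- familyMatrix(families)
  m <- ncol(f)
  if (n_folds < 2 || n_folds > m) stop("n_folds must lie in [2, n_families]")
  fam_of <- apply(f, 1, which.max)
  set.seed(.deriveSeed(seed, "folds"))
  fold_of_family <- sample(rep_len(seq_len(n_folds), m))
  all_ranks <- numeric(0)
  for (fold in seq_len(n_folds)) {
    test_fams <- which(fold_of_family == fold)
    train_rows <- which(!(fam_of %in% test_fams))
    x_train <- f[train_rows, -test_fams, drop = FALSE]
    keep <- colSums(x_train) > 0
    x_train <- x_train[, keep, drop = FALSE]
    cfg <- config
    cfg@seed <- .deriveSeed(config@seed, 1000L + fold)
    post <- brrrFit(y[train_rows, , drop = FALSE], x_train, cfg)
    emb <- latentEmbed(y, gammaMean(post), center = post@center)
    test_rows <- setdiff(seq_len(nrow(y)), train_rows)
    queries <- test_rows[vapply(test_rows, function(i)
      sum(fam_of == fam_of[i]) >= 2, TRUE)]
    if (!length(queries)) next
    related <- vapply(queries, function(i) {
      sibs <- setdiff(which(fam_of == fam_of[i]), i)
      sibs[1]
    }, 0L)
    exclude <- lapply(queries, function(i) which(fam_of == fam_of[i]))
    ranks <- .rankQueries(emb[queries, , drop = FALSE], emb, related, exclude,
                          n_unrelated, n_repeats,
                          .deriveSeed(seed, 2000L + fold))
    all_ranks <- c(all_ranks, ranks)
  }
  RankingSummary(all_ranks, n_unrelated + 1L, condition = "sibling",
                 K = config@K)
}

#' Self-identification across time segments
#'
#' Embeds two phenotype matrices computed from disjoint time segments of the
#' same participants with a common loading matrix, then ranks each
#' participant's segment-b embedding against unrelated candidates, querying
#' with the segment-a embedding.
#'
#' @param Y_a,Y_b phenotypes from two segments; identical participant sets
#'   in the same row order.
#' @param Gamma K x P loading matrix (e.g. `gammaMean()` of a fit); use
#'   `diag(P)` for the full-data baseline.
#' @param n_unrelated unrelated candidates per query (default 18).
#' @param n_repeats candidate resamplings per query (default 20).
#' @param seed candidate-sampling seed.
#' @param center feature means used for centering both segments; defaults to
#'   the column means of `Y_a`.
#' @return a \linkS4class{RankingSummary}.
#' @export
selfIdentification <- function(Y_a, Y_b, Gamma, n_unrelated = 18,
                               n_repeats = 20, seed = 1, center = NULL) {
  ya <- phenoMatrix(Y_a); yb <- phenoMatrix(Y_b)
  if (!identical(dim(ya), dim(yb)) ||
      !identical(rownames(ya), rownames(yb)))
    stop("segments must hold the same participants in the same order")
  if (is.null(center)) center <- colMeans(ya)
  za <- latentEmbed(ya, Gamma, center = center)
  zb <- latentEmbed(yb, Gamma, center = center)
  n <- nrow(za)
  ranks <- .rankQueries(za, zb, related_of = seq_len(n),
                        exclude_of = as.list(seq_len(n)),
                        n_unrelated, n_repeats, .deriveSeed(seed, "self"))
  RankingSummary(ranks, n_unrelated + 1L, condition = "self",
                 K = nrow(as.matrix(Gamma)))
}

#' Ranking accuracy as a function of segment length
#'
#' For each requested duration t, band powers are recomputed from the first
#' t seconds of every recording (and from the following disjoint t-second
#' window for self-identification); siblings are ranked through
#' cross-validated familial components and participants through
#' self-identification with loadings fitted on the first window. A full-data
#' baseline (L1 ranking on the raw band-power features, i.e. an identity
#' embedding) is computed alongside.
#'
#' @param recordings named list of samples x channels matrices, one per
#'   participant, with an `fs` attribute or `fs` supplied.
#' @param scheme a \linkS4class{BandScheme}.
#' @param durations_s numeric vector of segment lengths in seconds; every
#'   recording must cover `2 * max(durations_s)`.
#' @param families a \linkS4class{FamilyDesign}.
#' @param config a \linkS4class{BRRRConfig}.
#' @param fs sampling rate, Hz.
#' @param n_folds,n_unrelated,n_repeats,seed as in [familyCrossval()].
#' @return list with one element per duration, each a list of
#'   \linkS4class{RankingSummary} objects named `sibling`, `self` and
#'   `baseline_self`.
#' @export
segmentRankCurve <- function(recordings, scheme, durations_s, families,
                             config = BRRRConfig(), fs = NULL, n_folds = 5,
                             n_unrelated = 18, n_repeats = 20, seed = 1) {
  if (is.null(fs)) fs <- attr(recordings[[1]], "fs")
  n_min <- min(vapply(recordings, nrow, 0L))
  if (2 * max(durations_s) * fs > n_min)
    stop("recordings too short for duration ", max(durations_s), " s")
  out <- vector("list", length(durations_s))
  names(out) <- sprintf("%gs", durations_s)
  for (j in seq_along(durations_s)) {
    t_n <- round(durations_s[j] * fs)
    rec_a <- lapply(recordings, function(r) r[seq_len(t_n), , drop = FALSE])
    rec_b <- lapply(recordings, function(r) r[t_n + seq_len(t_n), , drop = FALSE])
    y_a <- spectraMatrix(rec_a, scheme, fs = fs, condition = "segment_a")
    y_b <- spectraMatrix(rec_b, scheme, fs = fs, condition = "segment_b")
    sib <- familyCrossval(y_a, families, config, n_folds = n_folds,
                          n_unrelated = n_unrelated, n_repeats = n_repeats,
                          seed = .deriveSeed(seed, 100L + j))
    sib@segmentLengthS <- durations_s[j]
    fit <- brrrFit(y_a, familyMatrix(families), {
      cfg <- config; cfg@seed <- .deriveSeed(config@seed, 200L + j); cfg
    })
    self <- selfIdentification(y_a, y_b, gammaMean(fit),
                               n_unrelated = n_unrelated,
                               n_repeats = n_repeats,
                               seed = .deriveSeed(seed, 300L + j),
                               center = fit@center)
    self@segmentLengthS <- durations_s[j]
    p <- ncol(phenoMatrix(y_a))
    base <- selfIdentification(y_a, y_b, diag(p),
                               n_unrelated = n_unrelated,
                               n_repeats = n_repeats,
                               seed = .deriveSeed(seed, 300L + j))
    base@condition <- "baseline_self"
    base@segmentLengthS <- durations_s[j]
    out[[j]] <- list(sibling = sib, self = self, baseline_self = base)
  }
  out
}
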