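## Periodogram band-power phenotyping: linearly widening frequency bands with
## the power-line band removed, Hamming-windowed full-segment periodogram,
## Parseval-consistent normalization (white-noise band powers sum to the
## signal variance).

#' Build a linearly widening band scheme
#'
#' Generates `n_bands_total` contiguous half-open bands starting at
#' `f_start`, with widths interpolated linearly from `w_first` to `w_last`,
#' then drops the single band containing `notch_hz` (power-line
#' interference). The defaults produce 21 retained bands starting at
#' `[1, 3)` Hz and ending at `[83, 89)` Hz.
#'
#' @param n_bands_total bands generated before the notch drop (>= 2).
#' @param f_start lower edge of the first band, Hz.
#' @param w_first,w_last widths of the first and last band, Hz.
#' @param notch_hz power-line frequency to excise (default 50 Hz); if no
#'   band contains it, nothing is dropped and a warning is raised.
#' @return a \linkS4class{BandScheme}.
#' @export
bandEdges <- function(n_bands_total = 22, f_start = 1, w_first = 2,
                      w_last = 6, notch_hz = 50) {
  if (n_bands_total < 2) stop("n_bands_total must be >= 2")
  if (w_first <= 0 || w_last <= 0) stop("band widths must be > 0")
  widths <- seq(w_first, w_last, length.out = n_bands_total)
  edges <- f_start + c(0, cumsum(widths))
  bands <- cbind(lo = edges[-length(edges)], hi = edges[-1])
  hit <- which(bands[, "lo"] <= notch_hz & notch_hz < bands[, "hi"])
  dropped <- numeric(0)
  if (length(hit) == 1L) {
    dropped <- bands[hit, ]
    bands <- bands[-hit, , drop = FALSE]
  } else {
    warning("no band contains the notch frequency ", notch_hz,
            " Hz; nothing dropped")
  }
  new("BandScheme", bands = bands, notchHz = notch_hz,
      dropped = as.numeric(dropped), nRetained = nrow(bands))
}

# Hamming-windowed one-sided periodogram of the full segment.
# Normalized so that sum(psd * df) over [0, Nyquist] equals
# sum(x^2 w^2)/sum(w^2), i.e. the (windowed) signal power.
.periodogram <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  w <- as.numeric(signal::hamming(n))
  xf <- stats::fft(x * w)
  u <- sum(w^2)
  nf <- floor(n / 2) + 1
  psd <- Mod(xf[seq_len(nf)])^2 / (fs * u)
  if (n %% 2 == 0) {
    if (nf > 2) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  } else {
    if (nf > 1) psd[2:nf] <- 2 * psd[2:nf]
  }
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd, df = fs / n)
}

# Sum spectral density over bins with centre frequency in [lo, hi).
.bandSum <- function(pg, lo, hi) {
  sel <- pg$freq >= lo & pg$freq < hi
  sum(pg$psd[sel]) * pg$df
}

#' Band power of a single time series
#'
#' Power in `[lo, hi)` Hz from a Hamming-windowed periodogram of the whole
#' segment. With this normalization the band powers of a white-noise signal
#' sum to its variance over the full `[0, Nyquist)` range (Parseval).
#'
#' @param x numeric time series.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric `(lo, hi)` with `lo < hi <= fs/2`.
#' @return non-negative scalar power (signal units squared).
#' @export
bandPower <- function(x, fs, band) {
  lo <- band[1]; hi <- band[2]
  if (!(lo < hi)) stop("band must satisfy lo < hi")
  if (hi > fs / 2 + 1e-12) stop("band upper edge above Nyquist ", fs / 2, " Hz")
  .bandSum(.periodogram(x, fs), lo, hi)
}

#' Spectral-power phenotype matrix from multichannel recordings
#'
#' One row per participant, columns ordered channel-major then band. Each
#' entry is the band power of that participant's channel in the scheme's
#' band, computed from one full-segment periodogram per channel.
#'
#' @param recordings named list, one element per participant, each a
#'   samples x channels numeric matrix. All participants must share the
#'   channel set.
#' @param scheme a \linkS4class{BandScheme}.
#' @param fs sampling rate in Hz; taken from the first recording's `fs`
#'   attribute when missing.
#' @param condition condition tag stored with the result.
#' @return a \linkS4class{SpectralPhenotype} with
#'   `P = n_channels * nRetained` columns labelled `<channel>_<lo>-<hi>Hz`.
#' @export
spectraMatrix <- function(recordings, scheme, fs = NULL,
                          condition = "unspecified") {
  if (!length(recordings)) stop("no recordings supplied")
  if (is.null(fs)) fs <- attr(recordings[[1]], "fs")
  if (is.null(fs)) stop("sampling rate 'fs' not supplied")
  bands <- bandMatrix(scheme)
  if (max(bands) > fs / 2 + 1e-12)
    stop("band scheme extends above Nyquist ", fs / 2, " Hz")
  ref <- colnames(recordings[[1]])
  if (is.null(ref)) ref <- sprintf("ch%03d", seq_len(ncol(recordings[[1]])))
  n_ch <- length(ref)
  lab <- as.vector(t(outer(ref, sprintf("%g-%gHz", bands[, 1], bands[, 2]),
                           paste, sep = "_")))
  ids <- names(recordings)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(recordings))
  y <- matrix(NA_real_, length(recordings), n_ch * nrow(bands),
              dimnames = list(ids, lab))
  for (i in seq_along(recordings)) {
    rec <- as.matrix(recordings[[i]])
    if (ncol(rec) != n_ch)
      stop("participant '", ids[i], "' has ", ncol(rec),
           " channels, expected ", n_ch)
    for (ch in seq_len(n_ch)) {
      pg <- .periodogram(rec[, ch], fs)
      y[i, (ch - 1) * nrow(bands) + seq_len(nrow(bands))] <-
        vapply(seq_len(nrow(bands)),
               function(b) .bandSum(pg, bands[b, 1], bands[b, 2]), 0)
    }
  }
  SpectralPhenotype(y, condition = condition)
}

#' Element-wise mean across experimental conditions
#'
#' @param phenos list of \linkS4class{SpectralPhenotype} objects with
#'   identical shapes and row order.
#' @return a \linkS4class{SpectralPhenotype} tagged `"mean_data"`.
#' @export
averageConditions <- function(phenos) {
  if (!length(phenos)) stop("empty phenotype list")
  ms <- lapply(phenos, phenoMatrix)
  d <- dim(ms[[1]])
  for (m in ms[-1]) {
    if (!identical(dim(m), d)) stop("phenotype shapes differ")
    if (!identical(rownames(m), rownames(ms[[1]])))
      stop("participant order differs between conditions")
  }
  avg <- Reduce(`+`, ms) / length(ms)
  SpectralPhenotype(avg, condition = "mean_data")
}
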