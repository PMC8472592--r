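# Slot "C" would partially match new()'s Class argument, so FeatureMaps
# objects are built via initialize() on an empty instance.
newFeatureMaps <- function(G, Qnorm, Wnorm, C, Cbin, CflowNorm, windowJ) {
  methods::initialize(methods::new("FeatureMaps"), G = G, Qnorm = Qnorm,
                      Wnorm = Wnorm, C = C, Cbin = Cbin,
                      CflowNorm = CflowNorm, windowJ = as.integer(windowJ))
}

# Per-window feature maps: gradient, pseudo-periodicity, RR clusters,
# correlation and covariance. Public operations accept a WindowView (or a
# plain M x L x N array); the detection engine calls the matrix-level
# internals directly with precomputed spectrum matrices.

winSamples <- function(window) {
  if (is(window, "WindowView")) window@samples else window
}

# ---- spectra ------------------------------------------------------------

# Real DFT matrices for an N-sample window zero-padded to nfft points;
# one-sided bins 0..nfft/2.
dftMatrices <- function(N, nfft = 512, rateHz = 9, bandBpm = c(30, 110)) {
  k <- 0:(nfft / 2)
  ang <- outer(k, 0:(N - 1), function(kk, nn) -2 * pi * kk * nn / nfft)
  bpm <- k * rateHz / nfft * 60
  inband <- which(bpm >= bandBpm[1] & bpm <= bandBpm[2])
  list(cos = cos(ang), sin = sin(ang), bpm = bpm, inband = inband)
}

# Amplitude-spectrum features per pixel for X (P x N, one pixel per row):
# Q = height of the in-band peak of the unit-sum-normalized amplitude
# spectrum; domBpm = frequency of that peak (NA for silent pixels).
spectralFeatures <- function(X, mats) {
  Xt <- t(X)
  Sc <- mats$cos %*% Xt
  Ss <- mats$sin %*% Xt
  A <- sqrt(Sc * Sc + Ss * Ss)
  total <- colSums(A)
  Ai <- A[mats$inband, , drop = FALSE]
  km <- max.col(t(Ai), ties.method = "first")
  peak <- Ai[cbind(km, seq_len(ncol(Ai)))]
  Q <- ifelse(total > 0, peak / total, 0)
  dom <- mats$bpm[mats$inband][km]
  dom[peak <= 0] <- NA_real_
  list(Q = Q, domBpm = dom)
}

# Normalize a non-negative map to [0, 1] by its maximum; an all-zero map
# stays zero and an all-equal map stays all ones.
normalizeByMax <- function(x) {
  mx <- max(x)
  if (mx > 0) x / mx else x
}

# ---- gradient -----------------------------------------------------------

#' Gradient (edge) map of the window-mean frame
#'
#' Marks the edges of the thermal image, where respiratory-motion pixels
#' live: Sobel gradient magnitude of the mean frame, thresholded at a
#' fraction \code{tauG} of its maximum and dilated by \code{dilate} pixels.
#' The flow map multiplies by \code{(J - G)}, so edge pixels get weight 0.
#'
#' @param meanFrame numeric M x L matrix (time-mean of the raw window).
#' @param tauG threshold fraction of the maximum gradient magnitude
#'   (default 0.2).
#' @param dilate dilation radius in pixels (default 1).
#' @return Binary (0/1) M x L matrix.
#' @export
gradientMap <- function(meanFrame, tauG = 0.2, dilate = 1L) {
  # spatial-domain Sobel (exact zeros on constant frames)
  p <- padReflect(meanFrame, 1L, 1L)
  n <- nrow(meanFrame); m <- ncol(meanFrame)
  sub <- function(dr, dc) p[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  G <- mag > tauG * mx & mx > 0
  if (dilate > 0) G <- dilateBinary(G, as.integer(dilate))
  storage.mode(G) <- "double"
  G
}

# ---- pseudo-periodicity -------------------------------------------------

#' Pseudo-periodicity map
#'
#' Per pixel, the amplitude spectrum of the window signal (zero-padded to
#' \code{nfft} points) is normalized to unit sum and the height of its peak
#' within the breathing band is taken; the map is then normalized to [0, 1]
#' by its maximum. High values mean the pixel's energy is concentrated at
#' one breathing frequency. All-zero pixels get 0.
#'
#' @param window a \code{\linkS4class{WindowView}} or M x L x N array of
#'   band-passed pixel signals.
#' @param filtered set \code{FALSE} if the samples still need band-pass
#'   filtering (applied per window in that case).
#' @param rateHz sampling rate (Hz).
#' @param bandBpm breathing band in BPM.
#' @param nfft zero-padded spectrum length.
#' @return Numeric M x L matrix in [0, 1].
#' @export
pseudoPeriodicityMap <- function(window, filtered = TRUE, rateHz = 9,
                                 bandBpm = c(30, 110), nfft = 512) {
  S <- winSamples(window)
  d <- dim(S)
  if (!filtered) S <- bandpassPixels(S, rateHz = rateHz, bandBpm = bandBpm)
  dim(S) <- c(d[1] * d[2], d[3])
  mats <- dftMatrices(d[3], nfft, rateHz, bandBpm)
  Q <- spectralFeatures(S, mats)$Q
  matrix(normalizeByMax(Q), d[1], d[2])
}

#' Dominant in-band frequency map
#'
#' Frequency (BPM) of the in-band amplitude-spectrum peak of every pixel;
#' NA for pixels with no spectral content.
#'
#' @inheritParams pseudoPeriodicityMap
#' @return Numeric M x L matrix of frequencies in BPM (NA where silent).
#' @export
dominantFrequencyMap <- function(window, rateHz = 9, bandBpm = c(30, 110),
                                 nfft = 512) {
  S <- winSamples(window)
  d <- dim(S)
  dim(S) <- c(d[1] * d[2], d[3])
  mats <- dftMatrices(d[3], nfft, rateHz, bandBpm)
  matrix(spectralFeatures(S, mats)$domBpm, d[1], d[2])
}

# Neighborhood agreement of dominant frequencies. domBpm: M x L (NA where
# undefined). Denominator is fixed at k^2 - 1; out-of-grid or undefined
# neighbours count as disagreeing, which naturally down-weights borders.
rrClustersFromFrequencies <- function(domBpm, k = 5L, deltaFBpm = 7.5) {
  r <- (k - 1L) %/% 2L
  agree <- matrix(0, nrow(domBpm), ncol(domBpm))
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    nb <- shiftMatrix(domBpm, dr, dc, fill = NA)
    hit <- !is.na(domBpm) & !is.na(nb) & abs(domBpm - nb) <= deltaFBpm
    agree <- agree + hit
  }
  W <- agree / (k^2 - 1)
  W[is.na(domBpm)] <- 0
  W
}

#' RR clusters map
#'
#' A 2-D non-linear filter detecting pixels whose neighbours breathe at the
#' same frequency: for each pixel, the fraction of the \code{k x k}
#' neighbourhood whose dominant in-band frequency lies within
#' \code{deltaFBpm} of the pixel's own, normalized to [0, 1] by the map
#' maximum. Coherent patches (nostril flow, textile flow) score high;
#' isolated periodic noise scores low.
#'
#' @inheritParams pseudoPeriodicityMap
#' @param k neighbourhood side length in pixels (odd, default 5).
#' @param deltaFBpm frequency agreement tolerance in BPM (default 7.5).
#' @return Numeric M x L matrix in [0, 1].
#' @export
rrClustersMap <- function(window, k = 5L, deltaFBpm = 7.5, rateHz = 9,
                          bandBpm = c(30, 110), nfft = 512) {
  dom <- dominantFrequencyMap(window, rateHz, bandBpm, nfft)
  normalizeByMax(rrClustersFromFrequencies(dom, k, deltaFBpm))
}

# ---- core pixel, correlation, covariance --------------------------------

#' Select the mixed-respiratory core-pixel
#'
#' The pixel that best represents the mixed respiratory signal: the argmax
#' of \code{Qnorm * Wnorm * (J - G)} (pseudo-periodicity times RR clusters,
#' with edge pixels zeroed). Ties break deterministically to the lowest row,
#' then lowest column.
#'
#' @param Qnorm,Wnorm,G M x L feature maps (see
#'   \code{\link{pseudoPeriodicityMap}}, \code{\link{rrClustersMap}},
#'   \code{\link{gradientMap}}).
#' @return Integer \code{c(row, col)} (1-based).
#' @export
selectCorePixel <- function(Qnorm, Wnorm, G) {
  stopifnot(all(dim(Qnorm) == dim(Wnorm)), all(dim(Qnorm) == dim(G)))
  prod <- Qnorm * Wnorm * (1 - G)
  if (max(prod) <= 0) stop("no candidate core-pixel (all-zero product)")
  argmaxPixel(prod)
}

# Pearson correlation of the core pixel's signal with every pixel signal.
# X: P x N matrix; coreIdx: linear pixel index. Zero-variance pixels get 0.
corMapMatrix <- function(X, coreIdx) {
  N <- ncol(X)
  y <- X[coreIdx, ]
  yc <- y - mean(y)
  sy <- sum(yc^2)
  if (sy <= 0) return(rep(0, nrow(X)))
  num <- as.vector(X %*% yc)
  sx <- rowSums(X^2) - N * rowMeans(X)^2
  sx[sx < 0] <- 0
  den <- sqrt(sx * sy)
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, -1), 1)
}

#' Correlation map against a core-pixel
#'
#' Pearson correlation coefficient between the core-pixel signal and every
#' pixel signal of the (band-passed) window. Zero-variance pixels get
#' correlation 0.
#'
#' @param window a \code{\linkS4class{WindowView}} or M x L x N array of
#'   band-passed signals.
#' @param core integer \code{c(row, col)} core-pixel position (1-based).
#' @return Numeric M x L matrix in [-1, 1].
#' @export
correlationMap <- function(window, core) {
  S <- winSamples(window)
  d <- dim(S)
  dim(S) <- c(d[1] * d[2], d[3])
  coreIdx <- core[1] + (core[2] - 1L) * d[1]
  matrix(corMapMatrix(S, coreIdx), d[1], d[2])
}

#' Binarize a correlation map
#'
#' Applies the empirical threshold \code{xi1} to the absolute correlation:
#' \code{|C| > xi1} (strict), so strongly anti-correlated pixels are kept
#' too -- the sign distinction is the covariance map's job.
#'
#' @param C correlation map from \code{\link{correlationMap}}.
#' @param xi1 threshold (default 0.6).
#' @return Binary (0/1) M x L matrix.
#' @export
binarizeCorrelation <- function(C, xi1 = 0.6) {
  out <- (abs(C) > xi1)
  storage.mode(out) <- "double"
  out
}

# Signed covariance of a reference signal with every pixel signal,
# normalized by the maximum absolute value. X: P x N; y: length-N signal of
# the previous window's flow-core-pixel (taken at the current window).
covMapMatrix <- function(X, y) {
  cv <- as.vector(X %*% y) / ncol(X)
  mx <- max(abs(cv))
  if (mx > 0) cv / mx else cv
}

#' Covariance map against the previous flow-core-pixel
#'
#' Each element is the covariance (mean product of the band-passed, hence
#' zero-mean, signals) between the flow-core-pixel chosen in the previous
#' window and the pixel at \code{(m, l)}, over the current window's samples,
#' normalized to [-1, 1] by the map's maximum absolute value. The sign is
#' kept: anti-phase pixels, which can only originate from motion, come out
#' negative and are rejected downstream. For the first window (no previous
#' core) the map is all ones.
#'
#' @param window a \code{\linkS4class{WindowView}} or M x L x N array of
#'   band-passed signals.
#' @param prevCore integer \code{c(row, col)} of the previous window's
#'   flow-core-pixel, or \code{NULL} for the first window.
#' @return Numeric M x L matrix in [-1, 1].
#' @export
covarianceMap <- function(window, prevCore = NULL) {
  S <- winSamples(window)
  d <- dim(S)
  if (is.null(prevCore)) return(matrix(1, d[1], d[2]))
  dim(S) <- c(d[1] * d[2], d[3])
  y <- S[prevCore[1] + (prevCore[2] - 1L) * d[1], ]
  matrix(covMapMatrix(S, y), d[1], d[2])
}

#' Assemble per-window feature maps
#'
#' Convenience wrapper computing all maps of one window at once; the
#' detection engine (\code{\link{analyzeVideo}}) does the same computation
#' incrementally across windows.
#'
#' @param window a \code{\linkS4class{WindowView}} of \emph{band-passed}
#'   signals.
#' @param rawMeanFrame M x L time-mean of the raw (unfiltered) window, for
#'   the gradient map.
#' @param prevCore previous window's flow-core-pixel or NULL.
#' @param config a \code{\link{runConfig}} list.
#' @return A \code{\linkS4class{FeatureMaps}} object.
#' @export
computeFeatureMaps <- function(window, rawMeanFrame, prevCore = NULL,
                               config = runConfig()) {
  S <- winSamples(window)
  j <- if (is(window, "WindowView")) window@j else 1L
  G <- gradientMap(rawMeanFrame, config$tauG, config$dilate)
  Qn <- pseudoPeriodicityMap(S, filtered = TRUE, rateHz = config$rateHz,
                             bandBpm = config$bandBpm, nfft = config$nfft)
  Wn <- rrClustersMap(S, k = config$neighborhood,
                      deltaFBpm = config$deltaFBpm, rateHz = config$rateHz,
                      bandBpm = config$bandBpm, nfft = config$nfft)
  core <- selectCorePixel(Qn, Wn, G)
  C <- correlationMap(S, core)
  newFeatureMaps(G = G, Qnorm = Qn, Wnorm = Wn, C = C,
                 Cbin = binarizeCorrelation(C, config$xi1),
                 CflowNorm = covarianceMap(S, prevCore), windowJ = j)
}
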