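#' Combine the five features into the flow map
#'
#' Elementwise product \code{FM = Cbin * CflowNorm * Qnorm * Wnorm * (J - G)}:
#' a pixel survives only if it correlates with the mixed-respiratory core,
#' co-varies in phase with the previous flow-core-pixel, is pseudo-periodic,
#' sits in a frequency-coherent neighbourhood, and is off the thermal edges.
#' Anti-phase pixels carry a negative sign through \code{CflowNorm} and are
#' removed by the strictly positive threshold in
#' \code{\link{binarizeFlowMap}}.
#'
#' @param Cbin,CflowNorm,Qnorm,Wnorm,G M x L feature maps sharing one shape.
#' @return Numeric M x L flow map in [-1, 1].
#' @export
flowMap <- function(Cbin, CflowNorm, Qnorm, Wnorm, G) {
  dims <- lapply(list(Cbin, CflowNorm, Qnorm, Wnorm, G), dim)
  if (length(unique(dims)) != 1L) stop("feature maps disagree on shape")
  Cbin * CflowNorm * Qnorm * Wnorm * (1 - G)
}

#' Binarize the flow map
#'
#' \code{FMhat = FM > xi2}, strict inequality (a pixel exactly at the
#' threshold is excluded). The supra-threshold pixels form the detected RF
#' set of the window.
#'
#' @param FM flow map from \code{\link{flowMap}}.
#' @param xi2 empirical threshold (default 0.2).
#' @return Binary (0/1) M x L matrix.
#' @export
binarizeFlowMap <- function(FM, xi2 = 0.2) {
  out <- FM > xi2
  storage.mode(out) <- "double"
  out
}

#' Run the full per-window analysis of a thermal video
#'
#' The engine behind \code{\link{detectRfPixels}} and
#' \code{\link{mrPixelsAndSignal}}; call it directly when both the RF and
#' the MR outputs are needed (e.g. for apnea-detection comparisons), so the
#' shared feature maps are computed once.
#'
#' Per 8 s window (1 s hop) it computes the gradient, pseudo-periodicity
#' and RR-clusters maps, the mixed-respiratory core-pixel and its
#' correlation map, the covariance map against the previous window's
#' flow-core-pixel, the flow map and its binarization, and the Gabor-bank
#' flow-core-pixel selection. Window 1 contributes only the flow-core-pixel
#' to the RF set; later windows contribute all supra-threshold flow-map
#' pixels, and when none passes (the detection conditions are strict) the
#' previous window's RF pixels and core are carried over. The RF (MR)
#' signal averages the band-passed signals of the window's RF (MR) pixels;
#' each 1 s hop appends its 9 new samples, the first window its full 72, so
#' the stitched signal is causal and aligned with the video samples.
#' Anti-correlated MR pixels are sign-flipped before averaging (else they
#' would cancel the in-phase ones); set \code{flipAntiphase = FALSE} to
#' disable.
#'
#' @param video a \code{\linkS4class{ThermalVideo}}; resampled to the
#'   configured uniform rate first if needed.
#' @param config a \code{\link{runConfig}} list of tunables.
#' @param keepMaps keep the per-window \code{\linkS4class{FeatureMaps}} and
#'   binarized flow maps (memory-hungry; for inspection and tests).
#' @param flipAntiphase sign-flip anti-correlated pixels in the MR average.
#' @return A \code{\linkS4class{FlowDetectionResult}} carrying both the RF
#'   and the MR per-window pixel sets and stitched signals.
#' @export
analyzeVideo <- function(video, config = runConfig(), keepMaps = FALSE,
                         flipAntiphase = TRUE) {
  if (!isUniformRate(video) ||
      is.null(videoMeta(video)$uniform_rate))
    video <- interpolateUniform(video, config$rateHz)
  rate <- videoMeta(video)$uniform_rate
  d <- dim(frames(video))
  M <- d[1]; L <- d[2]; Tn <- d[3]
  P <- M * L
  N <- round(config$windowS * rate)
  hop <- round(rate)
  if (Tn < N) stop("segment shorter than 8 s")
  nw <- (Tn - N) %/% hop + 1L

  X <- frames(video)
  dim(X) <- c(P, Tn)
  Xf <- t(bandpassPixels(t(X), rateHz = rate, bandBpm = config$bandBpm,
                         order = config$filterOrder))

  mats <- dftMatrices(N, config$nfft, rate, config$bandBpm)
  bank <- makeGaborBank(config$lambdas, config$thetas)
  pre <- gaborPrecompute(bank, M, L)

  pflow <- vector("list", nw)
  pm <- vector("list", nw)
  cores <- matrix(NA_integer_, nw, 2)
  mrCores <- matrix(NA_integer_, nw, 2)
  fallback <- logical(nw)
  mapsOut <- if (keepMaps) vector("list", nw) else list()
  rf <- numeric(0)
  mr <- numeric(0)
  prevCoreIdx <- NULL
  prevPflowIdx <- NULL
  prevPmIdx <- integer(0)
  prevPmSign <- numeric(0)

  for (j in seq_len(nw)) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + N)
    W <- Xf[, idx, drop = FALSE]
    rawMean <- matrix(rowMeans(X[, idx, drop = FALSE]), M, L)

    G <- gradientMap(rawMean, config$tauG, config$dilate)
    sf <- spectralFeatures(W, mats)
    Qn <- matrix(normalizeByMax(sf$Q), M, L)
    dom <- matrix(sf$domBpm, M, L)
    Wn <- normalizeByMax(rrClustersFromFrequencies(dom, config$neighborhood,
                                                   config$deltaFBpm))
    base <- Qn * Wn * (1 - G)
    mrCoreIdx <- NULL
    Cvec <- rep(0, P)
    if (max(base) > 0) {
      mrCore <- argmaxPixel(base)
      mrCores[j, ] <- mrCore
      mrCoreIdx <- mrCore[1] + (mrCore[2] - 1L) * M
      Cvec <- corMapMatrix(W, mrCoreIdx)
    }
    Cbin <- as.numeric(abs(Cvec) > config$xi1)

    Cflow <- if (j == 1L) rep(1, P)
             else covMapMatrix(W, W[prevCoreIdx, ])
    FM <- Cbin * Cflow * as.vector(Qn) * as.vector(Wn) * as.vector(1 - G)
    FMbin <- FM > config$xi2

    core <- NULL
    if (any(FMbin)) {
      core <- gaborArgmax(matrix(as.numeric(FMbin), M, L), pre)
    }
    if (is.null(core)) {
      if (j == 1L)
        stop("no candidate flow-core-pixel in the first window")
      core <- cores[j - 1L, ]
    }
    cores[j, ] <- core
    coreIdx <- core[1] + (core[2] - 1L) * M

    if (j == 1L) {
      pflowIdx <- coreIdx
    } else if (any(FMbin)) {
      pflowIdx <- which(FMbin)
    } else {
      pflowIdx <- prevPflowIdx
      fallback[j] <- TRUE
    }
    pflow[[j]] <- linToPixels(pflowIdx, M)

    if (!is.null(mrCoreIdx)) {
      pmIdx <- which(abs(Cvec) > config$xi1)
      pmSign <- if (flipAntiphase) sign(Cvec[pmIdx]) else rep(1, length(pmIdx))
    } else {
      pmIdx <- prevPmIdx
      pmSign <- prevPmSign
    }
    pm[[j]] <- linToPixels(pmIdx, M)

    wrf <- colMeans(Xf[pflowIdx, idx, drop = FALSE])
    wmr <- if (length(pmIdx))
      colMeans(Xf[pmIdx, idx, drop = FALSE] * pmSign)
    else rep(0, N)
    if (j == 1L) {
      rf <- wrf
      mr <- wmr
    } else {
      rf <- c(rf, wrf[(N - hop + 1L):N])
      mr <- c(mr, wmr[(N - hop + 1L):N])
    }

    if (keepMaps) {
      mapsOut[[j]] <- list(
        features = newFeatureMaps(G = G, Qnorm = Qn, Wnorm = Wn,
                                  C = matrix(Cvec, M, L),
                                  Cbin = matrix(Cbin, M, L),
                                  CflowNorm = matrix(Cflow, M, L),
                                  windowJ = j),
        FM = matrix(FM, M, L), FMbin = matrix(as.numeric(FMbin), M, L))
    }

    prevCoreIdx <- coreIdx
    prevPflowIdx <- pflowIdx
    prevPmIdx <- pmIdx
    prevPmSign <- pmSign
  }

  new("FlowDetectionResult",
      pflow = pflow, pm = pm, coreTrajectory = cores,
      mrCoreTrajectory = mrCores, fallback = fallback,
      rfSignal = SignalTrace(rf, rate, kind = "RF"),
      mrSignal = SignalTrace(mr, rate, kind = "MR"),
      windowStartS = as.numeric(seq_len(nw) - 1L),
      maps = mapsOut)
}

linToPixels <- function(idx, M) {
  out <- cbind(row = as.integer((idx - 1L) %% M + 1L),
               col = as.integer((idx - 1L) %/% M + 1L))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Detect respiratory-flow pixels and the RF signal
#'
#' Runs the per-window flow detection (see \code{\link{analyzeVideo}}) and
#' returns the RF pixel trajectory and the stitched RF signal.
#'
#' @inheritParams analyzeVideo
#' @return A \code{\linkS4class{FlowDetectionResult}}.
#' @examples
#' \donttest{
#' ph <- generatePhantom(defaultScenes("flow_only", durationS = 20))
#' res <- detectRfPixels(ph$video)
#' res
#' }
#' @export
detectRfPixels <- function(video, config = runConfig(), keepMaps = FALSE) {
  analyzeVideo(video, config = config, keepMaps = keepMaps)
}

#' Mixed-respiratory pixel set and MR signal
#'
#' Per window, a core-pixel is chosen from pseudo-periodicity, RR clusters
#' and the edge map, and every pixel whose absolute Pearson correlation with
#' it exceeds \code{xi1} joins the MR set; the MR signal averages those
#' pixels (anti-correlated ones sign-flipped unless \code{flipAntiphase} is
#' off). This mixes flow and motion pixels indiscriminately -- the
#' comparison signal the flow detector improves on.
#'
#' @inheritParams analyzeVideo
#' @return List with \code{pm} (per-window pixel sets) and \code{mrSignal}
#'   (a \code{\linkS4class{SignalTrace}}).
#' @export
mrPixelsAndSignal <- function(video, config = runConfig(),
                              flipAntiphase = TRUE) {
  res <- analyzeVideo(video, config = config, flipAntiphase = flipAntiphase)
  list(pm = res@pm, mrSignal = res@mrSignal)
}
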