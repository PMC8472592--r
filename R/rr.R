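#' Estimate the respiration rate of one window
#'
#' Frequency of the maximum of the zero-padded (512-point by default)
#' magnitude spectrum within the breathing band, in breaths per minute. The
#' estimate is the padded-bin centre without interpolation (bin spacing
#' \code{rateHz / nfft * 60}, about 1.05 BPM at the defaults), which keeps
#' the estimator exactly reproducible; set \code{refine = TRUE} for
#' three-point parabolic peak refinement. When the spectrum's global peak
#' lies outside the band the in-band peak is still returned but flagged via
#' the \code{lowConfidence} attribute. An all-zero window has no defined
#' rate and returns \code{NA}.
#'
#' @param x numeric window signal (72 samples at the defaults).
#' @param rateHz sampling rate in Hz.
#' @param bandBpm breathing band in BPM.
#' @param nfft zero-padded spectrum length.
#' @param refine use parabolic peak interpolation.
#' @return Respiration rate in BPM (or NA), with attribute
#'   \code{lowConfidence}.
#' @examples
#' t <- (0:71) / 9
#' estimateRr(sin(2 * pi * 1 * t))  # 60 BPM sinusoid
#' @export
estimateRr <- function(x, rateHz = 9, bandBpm = c(30, 110), nfft = 512,
                       refine = FALSE) {
  if (all(x == 0)) {
    out <- NA_real_
    attr(out, "lowConfidence") <- TRUE
    return(out)
  }
  A <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))[1:(nfft / 2 + 1)]
  bpm <- (0:(nfft / 2)) * rateHz / nfft * 60
  inband <- which(bpm >= bandBpm[1] & bpm <= bandBpm[2])
  k <- inband[which.max(A[inband])]
  est <- bpm[k]
  if (refine && k > 1 && k < length(A)) {
    a <- A[k - 1]; b <- A[k]; cc <- A[k + 1]
    den <- a - 2 * b + cc
    if (den < 0) est <- est + 0.5 * (a - cc) / den * rateHz / nfft * 60
  }
  nonDc <- which(bpm > 0)
  attr(est, "lowConfidence") <-
    A[nonDc[which.max(A[nonDc])]] > A[k] &&
    !(nonDc[which.max(A[nonDc])] %in% inband)
  est
}

#' Per-window respiration-rate trace of a signal
#'
#' Slides the standard 8 s window (1 s hop) over the trace and estimates
#' the RR of each window.
#'
#' @param trace a \code{\linkS4class{SignalTrace}} (or numeric vector with
#'   \code{rateHz} given).
#' @param rateHz sampling rate, taken from the trace when available.
#' @inheritParams estimateRr
#' @param windowS window length in seconds.
#' @return \code{data.frame} with columns \code{window_j}, \code{t_s}
#'   (window start), \code{rr_bpm} and \code{low_confidence}.
#' @export
rrTrace <- function(trace, rateHz = 9, bandBpm = c(30, 110), nfft = 512,
                    windowS = 8) {
  if (is(trace, "SignalTrace")) {
    v <- trace@values
    rateHz <- trace@rateHz
  } else v <- as.numeric(trace)
  N <- round(windowS * rateHz)
  hop <- round(rateHz)
  if (length(v) < N) stop("signal shorter than one window")
  nw <- (length(v) - N) %/% hop + 1L
  rr <- numeric(nw)
  lc <- logical(nw)
  for (j in seq_len(nw)) {
    e <- estimateRr(v[((j - 1) * hop + 1):((j - 1) * hop + N)], rateHz,
                    bandBpm, nfft)
    rr[j] <- as.numeric(e)
    lc[j] <- isTRUE(attr(e, "lowConfidence"))
  }
  data.frame(window_j = seq_len(nw), t_s = as.numeric(seq_len(nw) - 1),
             rr_bpm = rr, low_confidence = lc)
}

#' Mean absolute error between two RR traces
#'
#' Windows where either trace is NA are excluded pairwise.
#'
#' @param est,ref numeric vectors of per-window RR estimates (BPM), equal
#'   length.
#' @return MAE in BPM.
#' @examples
#' maeRr(c(60, 62), c(58, 62))  # 1.0
#' @export
maeRr <- function(est, ref) {
  if (is.data.frame(est)) est <- est$rr_bpm
  if (is.data.frame(ref)) ref <- ref$rr_bpm
  if (length(est) != length(ref)) stop("traces must have equal length")
  ok <- !is.na(est) & !is.na(ref)
  if (!any(ok)) stop("no overlapping valid windows")
  mean(abs(est[ok] - ref[ok]))
}
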