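#' Merge camera views into one image plane
#'
#' Stacks the frames of several pre-synchronized views along rows, in the
#' order given, so three 60 x 80 cameras become one 180 x 80 video. All views
#' must share the column count; the timestamps of the first video are used
#' (hardware synchronization is assumed to have happened upstream).
#'
#' @param videos list of \code{\linkS4class{ThermalVideo}} objects.
#' @return A single \code{\linkS4class{ThermalVideo}} with
#'   \code{M = sum(M_i)} rows.
#' @export
mergeViews <- function(videos) {
  if (is(videos, "ThermalVideo")) return(videos)
  stopifnot(length(videos) >= 1)
  if (length(videos) == 1L) return(videos[[1]])
  Ls <- vapply(videos, function(v) frameDim(v)[2], numeric(1))
  if (length(unique(Ls)) != 1L)
    stop("views disagree on column count: ", paste(Ls, collapse = ", "))
  Ts <- vapply(videos, nFrames, numeric(1))
  Tn <- min(Ts)
  parts <- lapply(videos, function(v) frames(v)[, , seq_len(Tn), drop = FALSE])
  M <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  L <- Ls[1]
  out <- array(0, c(M, L, Tn))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  meta <- videoMeta(videos[[1]])
  meta$camera_count <- length(videos)
  ThermalVideo(out, timestamps(videos[[1]])[seq_len(Tn)], meta = meta)
}

#' Resample each pixel signal to a uniform rate
#'
#' Per-pixel 1-D linear interpolation onto the grid \code{k / rate_hz},
#' \code{k = 0, 1, ...}, truncated at the last original timestamp (no
#' extrapolation). Compensates the camera's uneven ~8.7 Hz sampling; the
#' default target is 9 Hz. The output records \code{uniform_rate} in its
#' metadata.
#'
#' @param video a \code{\linkS4class{ThermalVideo}}.
#' @param rateHz target rate in Hz (default 9).
#' @return A uniformly sampled \code{\linkS4class{ThermalVideo}}.
#' @export
interpolateUniform <- function(video, rateHz = 9) {
  if (rateHz <= 0) stop("'rateHz' must be positive")
  ts <- timestamps(video)
  d <- dim(frames(video))
  t0 <- ts[1]
  tq <- t0 + seq(0, by = 1 / rateHz,
                 length.out = floor((ts[length(ts)] - t0) * rateHz) + 1L)
  X <- frames(video)
  dim(X) <- c(d[1] * d[2], d[3])
  i <- findInterval(tq, ts, rightmost.closed = TRUE)
  i[i >= length(ts)] <- length(ts) - 1L
  i[i < 1L] <- 1L
  w <- (tq - ts[i]) / (ts[i + 1L] - ts[i])
  out <- X[, i, drop = FALSE] * rep(1 - w, each = nrow(X)) +
    X[, i + 1L, drop = FALSE] * rep(w, each = nrow(X))
  dim(out) <- c(d[1], d[2], length(tq))
  meta <- videoMeta(video)
  meta$uniform_rate <- rateHz
  ThermalVideo(out, tq - t0, meta = meta)
}

#' Sliding 8-second windows over a uniformly sampled video
#'
#' Windows hold \code{N = 8 * rate} consecutive samples (72 at 9 Hz) and
#' advance in steps of 1 s; the last partial window is discarded. Window
#' \code{j} (1-based) starts at \code{(j - 1)} s, so a T-frame segment yields
#' \code{floor((T - N) / rate) + 1} windows.
#'
#' @param video a uniformly sampled \code{\linkS4class{ThermalVideo}}.
#' @param windowS window length in seconds (default 8).
#' @param hopS hop in seconds (default 1).
#' @return List of \code{\linkS4class{WindowView}} objects.
#' @export
slidingWindows <- function(video, windowS = 8, hopS = 1) {
  if (!isUniformRate(video))
    stop("'video' must be uniformly sampled; run interpolateUniform() first")
  rate <- videoMeta(video)$uniform_rate %||%
    (1 / diff(timestamps(video))[1])
  N <- round(windowS * rate)
  hop <- round(hopS * rate)
  Tn <- nFrames(video)
  if (Tn < N) stop("segment shorter than 8 s")
  nw <- (Tn - N) %/% hop + 1L
  X <- frames(video)
  lapply(seq_len(nw), function(j) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + N)
    new("WindowView", samples = X[, , idx, drop = FALSE], j = as.integer(j),
        startS = (j - 1) * hopS, rateHz = rate)
  })
}

#' Band-pass filter per-pixel signals in the breathing band
#'
#' Zero-phase (forward-backward) Butterworth band-pass, passband 30-110
#' breaths per minute (0.5-1.833 Hz), applied independently to every pixel
#' signal over the whole segment. Zero phase matters because the sign of the
#' covariance map carries the in-phase/anti-phase distinction. The filter
#' family and order are not dictated by the method; a 4th-order Butterworth
#' is the package default and both are configurable.
#'
#' @param x an \code{M x L x T} array, a \code{T x P} matrix of pixel
#'   signals in columns, or a numeric vector.
#' @param rateHz sampling rate in Hz.
#' @param bandBpm passband in breaths per minute.
#' @param order Butterworth order.
#' @return Filtered data with the same shape; per-pixel means are removed by
#'   the passband.
#' @export
bandpassPixels <- function(x, rateHz = 9, bandBpm = c(30, 110), order = 4) {
  bf <- signal::butter(order, (bandBpm / 60) / (rateHz / 2), type = "pass")
  # the per-pixel mean (tens of degrees) is removed first: the passband
  # discards DC anyway, and a large offset would dominate the forward-
  # backward filter's edge transients
  filt1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.null(dim(x))) return(filt1(x))
  if (length(dim(x)) == 2L) return(apply(x, 2L, filt1))
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  out <- t(apply(x, 1L, filt1))
  dim(out) <- d
  out
}

# Low-pass companion used by the apnea simulator (content below `cutBpm`).
lowpassTrace <- function(v, rateHz, cutBpm = 30, order = 4) {
  bf <- signal::butter(order, (cutBpm / 60) / (rateHz / 2), type = "low")
  signal::filtfilt(bf, v)
}
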