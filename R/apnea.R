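#' Simulate an obstructive apnea in a thermal video
#'
#' Replaces the annotated respiratory-flow pixels with noise-pixels from the
#' same video for \code{durationS} seconds centred in the segment: each
#' annotated pixel receives, inside the interval, a donor noise-pixel's
#' signal with its low-frequency content (below \code{cutBpm}) removed and
#' replaced by the original pixel's own low-frequency content, so the splice
#' is continuous in the slow thermal drift while the breathing-band content
#' disappears. Motion pixels and everything outside the boxes are left
#' bit-identical -- an obstructive apnea stops the airflow but not the
#' respiratory effort.
#'
#' Donor pixels are drawn deterministically (seeded) from pixels outside the
#' annotation and outside \code{exclude} (pass the detected
#' mixed-respiratory pixel set there so donors are genuine noise-pixels),
#' matched one-to-one to the annotated pixels.
#'
#' @param video a uniformly sampled \code{\linkS4class{ThermalVideo}} of at
#'   least 30 s.
#' @param boxes \code{\linkS4class{AnnotationBoxes}} marking the RF pixels.
#' @param durationS apnea duration in seconds (default 10).
#' @param cutBpm low-frequency split point in BPM (default 30, the lower
#'   band edge; zero-phase low-pass).
#' @param seed integer seed for the donor draw.
#' @param exclude optional 1-based \code{(row, col)} matrix of additional
#'   pixels the donors must avoid.
#' @return A new \code{\linkS4class{ThermalVideo}}; the simulated interval
#'   \code{c(start_s, end_s)} is recorded in \code{videoMeta()$oa_interval}.
#' @export
simulateOa <- function(video, boxes, durationS = 10, cutBpm = 30, seed = 1,
                       exclude = NULL) {
  if (!isUniformRate(video))
    stop("'video' must be uniformly sampled; run interpolateUniform() first")
  ts <- timestamps(video)
  if (ts[length(ts)] - ts[1] < 3 * durationS)
    stop("segment too short for a ", durationS, " s apnea with margin")
  d <- dim(frames(video))
  pann <- annotationPixels(boxes, d[1:2])
  if (nrow(pann) == 0) stop("annotation boxes are empty")
  rate <- videoMeta(video)$uniform_rate %||% (1 / diff(ts)[1])

  mid <- (ts[1] + ts[length(ts)]) / 2
  sel <- which(ts >= mid - durationS / 2 & ts < mid + durationS / 2)

  avoid <- pixelKeys(pann)
  if (!is.null(exclude)) avoid <- c(avoid, pixelKeys(exclude))
  allPix <- as.matrix(expand.grid(row = seq_len(d[1]), col = seq_len(d[2])))
  cand <- allPix[!(pixelKeys(allPix) %in% avoid), , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidate noise-pixels left")
  set.seed(seed)
  donors <- cand[sample.int(nrow(cand), nrow(pann),
                            replace = nrow(cand) < nrow(pann)), ,
                 drop = FALSE]

  X <- frames(video)
  dim(X) <- c(d[1] * d[2], d[3])
  out <- X
  annIdx <- pann[, 1] + (pann[, 2] - 1L) * d[1]
  donIdx <- donors[, 1] + (donors[, 2] - 1L) * d[1]
  for (i in seq_along(annIdx)) {
    orig <- X[annIdx[i], ]
    noise <- X[donIdx[i], ]
    spliced <- (noise - lowpassTrace(noise, rate, cutBpm)) +
      lowpassTrace(orig, rate, cutBpm)
    out[annIdx[i], sel] <- spliced[sel]
  }
  dim(out) <- d
  meta <- videoMeta(video)
  meta$oa_interval <- c(mid - durationS / 2, mid + durationS / 2) - ts[1]
  ThermalVideo(out, ts, meta = meta)
}

#' Detect cessations of breathing in a respiration signal
#'
#' A cessation shows as a sudden amplitude drop: the short-term standard
#' deviation (8 s sliding window, 1 s hop -- the same windowing as the RR
#' estimation) is compared with a long-term standard deviation, the median
#' of the short-term values inside a trailing 15 s window. The trailing
#' median must span more than the event, otherwise it would adapt to the
#' apnea while it is still ongoing; 15 s comfortably exceeds the 10 s
#' minimum cessation. A window is flagged when
#' \code{shortStd < alpha * longStd} (strict, so an all-zero signal never
#' fires); the per-sample detection mask marks the full span of every
#' flagged window. The rule is amplitude-scale invariant.
#'
#' @param trace a \code{\linkS4class{SignalTrace}} (or numeric vector).
#' @param rateHz sampling rate, taken from the trace when available.
#' @param shortS short-term window length in seconds (default 8).
#' @param longS long-term window length in seconds (default 15).
#' @param alpha detection threshold ratio (default 0.5).
#' @return A \code{\linkS4class{CobResult}}.
#' @export
cobDetect <- function(trace, rateHz = 9, shortS = 8, longS = 15,
                      alpha = 0.5) {
  if (is(trace, "SignalTrace")) {
    v <- trace@values
    rateHz <- trace@rateHz
  } else v <- as.numeric(trace)
  n <- length(v)
  if (n / rateHz < longS) stop("signal shorter than ", longS, " s")
  ns <- round(shortS * rateHz)
  hop <- round(rateHz)
  nw <- (n - ns) %/% hop + 1L
  shortStd <- vapply(seq_len(nw), function(j)
    stats::sd(v[((j - 1) * hop + 1):((j - 1) * hop + ns)]), numeric(1))
  nback <- as.integer(longS - shortS)  # short windows inside trailing longS
  longStd <- rep(NA_real_, nw)
  for (j in seq_len(nw)) {
    if (j > nback)
      longStd[j] <- stats::median(shortStd[(j - nback):j])
  }
  flag <- !is.na(longStd) & shortStd < alpha * longStd
  det <- logical(n)
  for (j in which(flag)) {
    det[((j - 1) * hop + 1):((j - 1) * hop + ns)] <- TRUE
  }
  new("CobResult", detection = det, shortStd = shortStd, longStd = longStd,
      windowStartS = as.numeric(seq_len(nw) - 1L), alpha = alpha,
      rateHz = rateHz)
}

#' Time-based detection metrics against a template
#'
#' Compares a binary detection mask with a template that is 1 inside the
#' true event, counting durations: sensitivity \code{SE = TP / (TP + FN)},
#' specificity \code{SP = TN / (TN + FP)}, accuracy
#' \code{ACC = (TP + TN) / total}, all in percent. With no positive
#' (negative) template time, SE (SP) is undefined and reported as NA.
#'
#' @param detection logical/0-1 per-sample detection mask.
#' @param template logical/0-1 per-sample event template, same length.
#' @param rateHz sampling rate (only scales durations; the percentages are
#'   rate-free).
#' @return Named numeric vector \code{c(acc, se, sp)} in percent.
#' @examples
#' templateMetrics(rep(0, 60), c(rep(0, 25), rep(1, 10), rep(0, 25)), 1)
#' @export
templateMetrics <- function(detection, template, rateHz = 9) {
  detection <- as.logical(detection)
  template <- as.logical(template)
  if (length(detection) != length(template))
    stop("detection and template must have equal length")
  tp <- sum(detection & template) / rateHz
  fp <- sum(detection & !template) / rateHz
  tn <- sum(!detection & !template) / rateHz
  fn <- sum(!detection & template) / rateHz
  c(acc = 100 * (tp + tn) / (tp + fp + tn + fn),
    se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}
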