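# Synthetic thermal phantom: ground-truthed videos with the statistical
# structure the detector assumes. A scene holds a static background (spatial
# ramp plus a warm body ellipse with a sharp boundary), one or more
# respiratory-flow blobs (smooth circular Gaussians whose amplitude
# oscillates at the breathing rate -- thermal diffusion of exhaled air), a
# respiratory-motion source (the body-ellipse boundary ring oscillating in
# phase or anti-phase, with a weak decaying modulation halo around it), and
# per-pixel sensor noise, sampled unevenly at ~8.7 Hz.

#' Phantom scene configuration
#'
#' All randomness derives from \code{seed}; the same configuration always
#' yields a bit-identical video. Defaults model the study conditions: a
#' 180 x 80 merged frame, uneven sampling at a mean 8.7 Hz, breathing in
#' the 30-110 BPM band, a ~0.4 degC flow oscillation at the nostril/textile
#' region against ~0.05 degC sensor noise.
#'
#' @param grid \code{c(M, L)} frame size in pixels.
#' @param durationS scene length in seconds.
#' @param rrBpm breathing rate: a scalar (BPM) or a function of time
#'   returning BPM, within 30-110.
#' @param flowBlobs list of blobs, each
#'   \code{list(center = c(row, col), sigmaPx, ampDegC)}; \code{NULL} places
#'   one default blob above the body ellipse.
#' @param motionEdges list of motion sources, each
#'   \code{list(pixels = (row, col) matrix, ampDegC = scalar or per-pixel
#'   vector, phase = 0 or pi)}; \code{"body"} builds the body-boundary ring
#'   with its diffusion halo (in phase), \code{"body_antiphase"} the same in
#'   anti-phase.
#' @param noiseSigmaDegC per-pixel Gaussian sensor noise (NETD scale).
#' @param meanRateHz mean frame rate of the uneven sampling.
#' @param jitterFrac frame-interval jitter as a fraction of the mean
#'   interval (uniform).
#' @param apneaIntervals list of \code{c(start_s, end_s)}: flow amplitude is
#'   exactly 0 inside (half-open); motion persists (obstructive apnea).
#' @param seed integer seed.
#' @param baseDegC background temperature offset.
#' @param rampDegC amplitude of the smooth horizontal background ramp.
#' @param body \code{list(center, semi = c(a, b), deltaDegC)} for the warm
#'   body ellipse; \code{NULL} for the default proportions.
#' @param annotationPadPx margin (pixels) added around each flow blob's
#'   mask bounding box when deriving the annotation boxes, emulating the
#'   generosity of a human annotator who boxes every visibly flickering
#'   pixel.
#' @return A list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(grid = c(180, 80), durationS = 60, rrBpm = 48,
                          flowBlobs = NULL, motionEdges = list(),
                          noiseSigmaDegC = 0.05, meanRateHz = 8.7,
                          jitterFrac = 0.2, apneaIntervals = NULL,
                          seed = 1, baseDegC = 31, rampDegC = 1,
                          body = NULL, annotationPadPx = 2L) {
  if (is.null(body))
    body <- list(center = round(grid * c(0.56, 0.5)),
                 semi = round(grid * c(0.27, 0.28)),
                 deltaDegC = 4)
  if (is.null(flowBlobs))
    flowBlobs <- list(list(
      center = c(max(body$center[1] - body$semi[1] - 8, 7), body$center[2]),
      sigmaPx = 3, ampDegC = 0.4))
  cfg <- list(grid = as.integer(grid), durationS = durationS, rrBpm = rrBpm,
              flowBlobs = flowBlobs, motionEdges = motionEdges,
              noiseSigmaDegC = noiseSigmaDegC, meanRateHz = meanRateHz,
              jitterFrac = jitterFrac, apneaIntervals = apneaIntervals,
              seed = seed, baseDegC = baseDegC, rampDegC = rampDegC,
              body = body, annotationPadPx = as.integer(annotationPadPx))
  class(cfg) <- "PhantomConfig"
  cfg
}

bodyInsideMask <- function(cfg) {
  M <- cfg$grid[1]; L <- cfg$grid[2]
  r <- matrix(seq_len(M), M, L)
  cc <- matrix(seq_len(L), M, L, byrow = TRUE)
  ((r - cfg$body$center[1]) / cfg$body$semi[1])^2 +
    ((cc - cfg$body$center[2]) / cfg$body$semi[2])^2 <= 1
}

# Motion source at the body-ellipse boundary: the sharp edge oscillates
# with Gaussian-decaying amplitude within +-1.5 px of the boundary (where
# the gradient feature masks it), and a weak diffuse patch -- fabric
# shifting with the respiratory effort near, but off, the edge -- sits at
# Euclidean distance 3-4 px outside the body, restricted to a short arc on
# the upper-right flank. Distances are a true Euclidean distance transform
# from the boundary ring.
bodyEdgeSource <- function(cfg, phase = 0, ampDegC = 0.4,
                           edgeSigmaPx = 1.5, haloAmpDegC = 0.055,
                           haloRangePx = c(3, 4),
                           haloAngleDeg = c(40, 85)) {
  inside <- bodyInsideMask(cfg)
  ring <- inside & !(shiftMatrix(inside, 1, 0, TRUE) &
                     shiftMatrix(inside, -1, 0, TRUE) &
                     shiftMatrix(inside, 0, 1, TRUE) &
                     shiftMatrix(inside, 0, -1, TRUE))
  M <- cfg$grid[1]; L <- cfg$grid[2]
  rp <- maskToPixels(ring)
  r <- matrix(seq_len(M), M, L)
  cc <- matrix(seq_len(L), M, L, byrow = TRUE)
  D <- matrix(Inf, M, L)
  for (i in seq_len(nrow(rp)))
    D <- pmin(D, sqrt((r - rp[i, 1])^2 + (cc - rp[i, 2])^2))
  amp <- matrix(0, M, L)
  edge <- D <= 1.5
  amp[edge] <- ampDegC * exp(-D[edge]^2 / (2 * edgeSigmaPx^2))
  # polar angle from the ellipse centre, 0 = straight up, clockwise
  ang <- atan2(cc - cfg$body$center[2], -(r - cfg$body$center[1])) * 180 / pi
  halo <- D >= haloRangePx[1] & D <= haloRangePx[2] & !inside &
    ang >= haloAngleDeg[1] & ang <= haloAngleDeg[2]
  amp[halo] <- haloAmpDegC
  pixels <- maskToPixels(amp > 0)
  list(pixels = pixels, ampDegC = amp[amp > 0], phase = phase)
}

blobField <- function(cfg, blob) {
  M <- cfg$grid[1]; L <- cfg$grid[2]
  r <- matrix(seq_len(M), M, L)
  cc <- matrix(seq_len(L), M, L, byrow = TRUE)
  d2 <- (r - blob$center[1])^2 + (cc - blob$center[2])^2
  blob$ampDegC * exp(-d2 / (2 * blob$sigmaPx^2))
}

resolveMotionEdges <- function(cfg) {
  lapply(cfg$motionEdges, function(e) {
    if (identical(e, "body")) bodyEdgeSource(cfg, phase = 0)
    else if (identical(e, "body_antiphase")) bodyEdgeSource(cfg, phase = pi)
    else e
  })
}

#' Generate a synthetic thermal phantom
#'
#' Builds the frames, the uneven timestamps, the ground-truth flow and
#' motion masks (pixels receiving at least 20\% of the source's peak
#' amplitude -- a reproducible stand-in for a human annotator's judgement),
#' the per-window true respiration rate, and annotation boxes (one bounding
#' box per flow blob, in the standard 0-based half-open convention).
#'
#' Flow and motion share a single global breathing phase (one subject);
#' motion sources may be phase-shifted by pi to model anti-phase edges
#' (e.g. the blanket/face boundary, where warm pixels cool during
#' inhalation). During configured apnea intervals the flow amplitude is
#' exactly zero while motion persists.
#'
#' @param cfg a \code{\link{phantomConfig}} list.
#' @return List with \code{video} (\code{\linkS4class{ThermalVideo}}),
#'   \code{flowMask}, \code{motionMask} (logical M x L), \code{rrTruth}
#'   (data.frame \code{t_s, rr_bpm}, one row per 8 s window at 1 s hop),
#'   \code{annotations} (\code{\linkS4class{AnnotationBoxes}}) and the
#'   expanded \code{config}.
#' @export
generatePhantom <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  M <- cfg$grid[1]; L <- cfg$grid[2]
  for (b in cfg$flowBlobs) {
    if (b$center[1] < 1 || b$center[1] > M || b$center[2] < 1 ||
        b$center[2] > L)
      stop("flow blob centre outside the ", M, " x ", L, " grid")
    if (b$center[1] < 2 * b$sigmaPx || b$center[1] > M - 2 * b$sigmaPx ||
        b$center[2] < 2 * b$sigmaPx || b$center[2] > L - 2 * b$sigmaPx)
      stop("flow blob closer than 2 sigma to the frame border")
  }
  set.seed(cfg$seed)

  # uneven timestamps, mean rate meanRateHz
  meanDt <- 1 / cfg$meanRateHz
  n <- ceiling(cfg$durationS / meanDt) + 8L
  gaps <- meanDt * (1 + cfg$jitterFrac * stats::runif(n, -0.5, 0.5))
  ts <- cumsum(c(0, gaps))
  ts <- ts[ts <= cfg$durationS]
  Tn <- length(ts)

  # single global breathing phase
  rrFun <- if (is.function(cfg$rrBpm)) cfg$rrBpm else function(t)
    rep(cfg$rrBpm, length(t))
  rr <- rrFun(ts)
  dphi <- c(0, diff(ts)) * rr / 60
  phase <- 2 * pi * cumsum(dphi)
  sFlow <- sin(phase)
  for (iv in cfg$apneaIntervals)
    sFlow[ts >= iv[1] & ts < iv[2]] <- 0

  # static background
  r <- matrix(seq_len(M), M, L)
  cc <- matrix(seq_len(L), M, L, byrow = TRUE)
  static <- cfg$baseDegC + cfg$rampDegC * (cc - 1) / max(L - 1, 1) +
    cfg$body$deltaDegC * bodyInsideMask(cfg)

  P <- M * L
  X <- matrix(static, P, Tn)

  flowField <- matrix(0, M, L)
  flowMask <- matrix(FALSE, M, L)
  boxes <- NULL
  for (b in cfg$flowBlobs) {
    f <- blobField(cfg, b)
    flowField <- flowField + f
    bm <- f >= 0.2 * b$ampDegC
    flowMask <- flowMask | bm
    # annotation box: the mask's bounding box plus a small margin -- a
    # human annotator boxes every visibly flickering pixel, which reaches
    # a little beyond the 20%-amplitude mask
    pad <- cfg$annotationPadPx %||% 2L
    px <- maskToPixels(bm)
    boxes <- rbind(boxes, c(max(min(px[, 1]) - 1L - pad, 0L),
                            max(min(px[, 2]) - 1L - pad, 0L),
                            min(max(px[, 1]) + pad, M),
                            min(max(px[, 2]) + pad, L)))
  }
  X <- X + as.vector(flowField) %*% t(sFlow)

  motionMask <- matrix(FALSE, M, L)
  for (e in resolveMotionEdges(cfg)) {
    amps <- rep(e$ampDegC, length.out = nrow(e$pixels))
    idx <- e$pixels[, 1] + (e$pixels[, 2] - 1L) * M
    sEdge <- sin(phase + e$phase)
    X[idx, ] <- X[idx, ] + amps %*% t(sEdge)
    keep <- amps >= 0.2 * max(amps)
    motionMask[idx[keep]] <- TRUE
  }

  if (cfg$noiseSigmaDegC > 0)
    X <- X + matrix(stats::rnorm(P * Tn, sd = cfg$noiseSigmaDegC), P, Tn)

  dim(X) <- c(M, L, Tn)
  video <- ThermalVideo(X, ts, meta = list(
    unit = "C", segment_id = paste0("phantom_seed", cfg$seed),
    mean_rate = cfg$meanRateHz))

  nwin <- max(floor(cfg$durationS) - 8L + 1L, 1L)
  wstart <- seq_len(nwin) - 1
  rrWin <- vapply(wstart, function(s) {
    tt <- seq(s, s + 8, by = 0.1)
    mean(rrFun(tt))
  }, numeric(1))

  list(video = video, flowMask = flowMask, motionMask = motionMask,
       rrTruth = data.frame(t_s = wstart, rr_bpm = rrWin),
       annotations = AnnotationBoxes(boxes,
                                     segmentId = paste0("phantom_seed",
                                                        cfg$seed),
                                     dim = c(M, L)),
       config = cfg)
}

#' Named phantom scene presets
#'
#' Fixed single-view (60 x 80) scenes exercising the detector's failure and
#' success modes:
#' \describe{
#'   \item{flow_only}{one flow blob, no motion source.}
#'   \item{flow_plus_inphase_motion}{flow blob plus the body-boundary
#'     motion source oscillating in phase with the flow.}
#'   \item{flow_plus_antiphase_motion}{the same motion source in
#'     anti-phase.}
#'   \item{nostril_on_edge}{the flow blob centred on the body boundary, so
#'     edge removal swallows it (the known hard case of nostril flow seen
#'     edge-on).}
#'   \item{apnea_10s}{flow plus in-phase motion, with the flow amplitude
#'     exactly 0 on 25-35 s of a 60 s scene (a simulated obstructive
#'     apnea).}
#' }
#'
#' @param name preset name.
#' @param durationS scene length (default 60 s).
#' @param seed seed override (each preset's default is 1).
#' @return A \code{\link{phantomConfig}}.
#' @export
defaultScenes <- function(name, durationS = 60, seed = 1) {
  grid <- c(60, 80)
  body <- list(center = c(40, 40), semi = c(12, 22), deltaDegC = 4)
  blob <- list(center = c(14, 40), sigmaPx = 3, ampDegC = 0.4)
  base <- function(...) phantomConfig(grid = grid, durationS = durationS,
                                      seed = seed, body = body, ...)
  switch(name,
    flow_only = base(flowBlobs = list(blob)),
    flow_plus_inphase_motion = base(flowBlobs = list(blob),
                                    motionEdges = list("body")),
    flow_plus_antiphase_motion = base(flowBlobs = list(blob),
                                      motionEdges = list("body_antiphase")),
    nostril_on_edge = base(flowBlobs = list(list(center = c(28, 40),
                                                 sigmaPx = 3,
                                                 ampDegC = 0.4))),
    apnea_10s = base(flowBlobs = list(blob), motionEdges = list("body"),
                     apneaIntervals = list(c(25, 35))),
    stop("unknown scene preset: ", name))
}
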