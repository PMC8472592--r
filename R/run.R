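#' Pipeline configuration
#'
#' All tunables of the detection pipeline with their defaults. The
#' correlation threshold \code{xi1 = 0.6} and flow-map threshold
#' \code{xi2 = 0.2} are the method's empirical values; the band is the
#' expected infant breathing range 30-110 BPM; the Gabor wavelengths and
#' orientations are the bank's standard grid; 8 s / 15 s are the short and
#' long cessation-detector windows.
#'
#' @param xi1 correlation-map binarization threshold.
#' @param xi2 flow-map binarization threshold.
#' @param bandBpm breathing band in BPM.
#' @param lambdas Gabor wavelengths (pixels/cycle).
#' @param thetas Gabor orientations (degrees).
#' @param shortStdS,longStdS cessation-detector window lengths (s).
#' @param alpha cessation threshold ratio.
#' @param rateHz uniform resampling rate (Hz).
#' @param windowS analysis window length (s).
#' @param nfft zero-padded spectrum length.
#' @param tauG gradient threshold fraction.
#' @param dilate gradient dilation radius (pixels).
#' @param neighborhood RR-clusters neighbourhood side (pixels).
#' @param deltaFBpm RR-clusters frequency tolerance (BPM).
#' @param filterOrder Butterworth band-pass order.
#' @param seed seed for the stochastic stages (phantom generation, apnea
#'   simulation); the detection itself is deterministic.
#' @return Named list of class \code{RunConfig}.
#' @export
runConfig <- function(xi1 = 0.6, xi2 = 0.2, bandBpm = c(30, 110),
                      lambdas = 3:8, thetas = seq(10, 170, by = 10),
                      shortStdS = 8, longStdS = 15, alpha = 0.5,
                      rateHz = 9, windowS = 8, nfft = 512, tauG = 0.2,
                      dilate = 1L, neighborhood = 5L, deltaFBpm = 7.5,
                      filterOrder = 4, seed = 1L) {
  cfg <- list(xi1 = xi1, xi2 = xi2, bandBpm = bandBpm, lambdas = lambdas,
              thetas = thetas, shortStdS = shortStdS, longStdS = longStdS,
              alpha = alpha, rateHz = rateHz, windowS = windowS,
              nfft = nfft, tauG = tauG, dilate = dilate,
              neighborhood = neighborhood, deltaFBpm = deltaFBpm,
              filterOrder = filterOrder, seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

pixelsToJsonList <- function(px) {
  lapply(seq_len(nrow(px)), function(i) as.integer(px[i, ] - 1L))
}

#' Run the detection pipeline on a video file
#'
#' Reads a thermal-video container, runs \code{\link{analyzeVideo}} and
#' writes \code{rf_signal.csv}, \code{mr_signal.csv}, \code{rr.csv},
#' \code{pflow.json} (per-window 0-based pixel lists) and
#' \code{config.json} to \code{outDir}. With annotations, per-window
#' PF/PM scores go to \code{scores.csv}. Outputs are deterministic for a
#' fixed config and seed.
#'
#' @param videoPath path to a thermal-video container (or a
#'   \code{\linkS4class{ThermalVideo}}).
#' @param outDir output directory (created if missing).
#' @param config a \code{\link{runConfig}}.
#' @param annotationsPath optional annotation JSON (or
#'   \code{\linkS4class{AnnotationBoxes}}).
#' @return Invisibly, the \code{\linkS4class{FlowDetectionResult}}.
#' @export
runDetect <- function(videoPath, outDir, config = runConfig(),
                      annotationsPath = NULL) {
  video <- if (is(videoPath, "ThermalVideo")) videoPath
           else readThermalVideo(videoPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- analyzeVideo(video, config = config)
  writeSignalTrace(res@rfSignal, file.path(outDir, "rf_signal.csv"))
  writeSignalTrace(res@mrSignal, file.path(outDir, "mr_signal.csv"))

  rrRf <- rrTrace(res@rfSignal, bandBpm = config$bandBpm,
                  nfft = config$nfft)
  rrMr <- rrTrace(res@mrSignal, bandBpm = config$bandBpm,
                  nfft = config$nfft)
  rr <- rbind(cbind(rrRf, source = "RF"), cbind(rrMr, source = "MR"))
  utils::write.csv(format(rr, digits = 10, trim = TRUE),
                   file.path(outDir, "rr.csv"), row.names = FALSE,
                   quote = FALSE)

  jsonlite::write_json(
    list(segment_id = videoMeta(video)$segment_id %||% "segment",
         seed = config$seed,
         windows = lapply(seq_along(res@pflow), function(j)
           list(window_j = j, fallback = res@fallback[j],
                pflow = pixelsToJsonList(res@pflow[[j]])))),
    file.path(outDir, "pflow.json"), auto_unbox = TRUE, digits = NA)
  writeRunConfig(config, file.path(outDir, "config.json"))

  if (!is.null(annotationsPath)) {
    ann <- if (is(annotationsPath, "AnnotationBoxes")) annotationsPath
           else readAnnotations(annotationsPath)
    pann <- annotationPixels(ann, frameDim(video))
    sc <- aggregateScores(res, pann)
    df <- rbind(sc$perWindow,
                data.frame(window_j = NA, pf = sc$pf, pm = sc$pm))
    utils::write.csv(format(df, digits = 10, trim = TRUE),
                     file.path(outDir, "scores.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(res)
}

#' Generate a phantom scene and write it to disk
#'
#' Writes the video container (with the ground-truth masks as extra
#' arrays), \code{rr_truth.csv} and \code{annotations.json}.
#'
#' @param scene a preset name (see \code{\link{defaultScenes}}) or a
#'   \code{\link{phantomConfig}}.
#' @param outDir output directory.
#' @param seed seed override for preset scenes.
#' @return Invisibly, the phantom list from \code{\link{generatePhantom}}.
#' @export
runPhantom <- function(scene, outDir, seed = 1) {
  cfg <- if (inherits(scene, "PhantomConfig")) scene
         else defaultScenes(scene, seed = seed)
  ph <- generatePhantom(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeThermalVideo(ph$video, file.path(outDir, "video.thv"),
                    extras = list(flow_mask = ph$flowMask + 0,
                                  motion_mask = ph$motionMask + 0))
  utils::write.csv(format(ph$rrTruth, digits = 10, trim = TRUE),
                   file.path(outDir, "rr_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  writeAnnotations(ph$annotations, file.path(outDir, "annotations.json"))
  invisible(ph)
}

#' Simulated-apnea evaluation of the three respiration signals
#'
#' The proof-of-concept comparison: obtain the RF and MR signals from the
#' video, the RefRF signal by averaging the annotated pixels, run the
#' cessation-of-breathing detector on each, and score the detections
#' against the event template with time-based ACC/SE/SP.
#'
#' With \code{simulate = TRUE} an obstructive apnea is first injected with
#' \code{\link{simulateOa}} (donor pixels avoid the detected MR set) and
#' the template marks the injected interval. With \code{simulate = FALSE}
#' the video is used as-is and \code{template} (a \code{c(start_s, end_s)}
#' interval or per-sample mask) must describe the true event -- the mode
#' used for phantoms whose flow amplitude is already zeroed.
#'
#' @param video a \code{\linkS4class{ThermalVideo}} or container path.
#' @param boxes \code{\linkS4class{AnnotationBoxes}} or annotation JSON
#'   path.
#' @param config a \code{\link{runConfig}}.
#' @param outDir optional output directory for \code{metrics.csv} and
#'   \code{apnea_events.json}.
#' @param simulate inject an obstructive apnea first.
#' @param template true-event interval \code{c(start_s, end_s)} or
#'   per-sample 0/1 mask (required when \code{simulate = FALSE}).
#' @param seed seed for the donor-pixel draw.
#' @return List with \code{metrics} (data.frame with rows RF, RefRF, MR),
#'   \code{cob} (per-signal \code{\linkS4class{CobResult}}), the
#'   \code{template} mask and the (possibly modified) \code{video}.
#' @export
runApneaEval <- function(video, boxes, config = runConfig(),
                         outDir = NULL, simulate = TRUE, template = NULL,
                         seed = config$seed) {
  if (!is(video, "ThermalVideo")) video <- readThermalVideo(video)
  if (!is(boxes, "AnnotationBoxes")) boxes <- readAnnotations(boxes)
  if (!isUniformRate(video) || is.null(videoMeta(video)$uniform_rate))
    video <- interpolateUniform(video, config$rateHz)
  rate <- videoMeta(video)$uniform_rate

  if (simulate) {
    pre <- analyzeVideo(video, config = config)
    pmAll <- unique(do.call(rbind, pre@pm))
    video <- simulateOa(video, boxes, seed = seed, exclude = pmAll)
    template <- videoMeta(video)$oa_interval
  }
  if (is.null(template))
    stop("'template' is required when simulate = FALSE")

  res <- analyzeVideo(video, config = config)
  n <- length(res@rfSignal@values)
  tt <- (seq_len(n) - 1) / rate
  tmpl <- if (length(template) == 2 && !is.logical(template))
    tt >= template[1] & tt < template[2]
  else as.logical(template)[seq_len(n)]

  d <- dim(frames(video))
  pann <- annotationPixels(boxes, d[1:2])
  X <- frames(video)
  dim(X) <- c(d[1] * d[2], d[3])
  annIdx <- pann[, 1] + (pann[, 2] - 1L) * d[1]
  refVals <- rowMeans(bandpassPixels(t(X[annIdx, , drop = FALSE]),
                                     rateHz = rate,
                                     bandBpm = config$bandBpm,
                                     order = config$filterOrder))
  refSig <- SignalTrace(refVals[seq_len(n)], rate, kind = "RefRF")

  sigs <- list(RF = res@rfSignal, RefRF = refSig, MR = res@mrSignal)
  cob <- lapply(sigs, cobDetect, shortS = config$shortStdS,
                longS = config$longStdS, alpha = config$alpha)
  metrics <- do.call(rbind, lapply(names(sigs), function(nm) {
    m <- templateMetrics(cob[[nm]]@detection, tmpl, rate)
    data.frame(signal = nm, acc = m["acc"], se = m["se"], sp = m["sp"],
               row.names = NULL)
  }))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(format(metrics, digits = 10, trim = TRUE),
                     file.path(outDir, "metrics.csv"), row.names = FALSE,
                     quote = FALSE)
    events <- lapply(names(cob), function(nm) {
      m <- cob[[nm]]@detection
      runs <- rle(m)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      keep <- which(runs$values)
      list(signal = nm,
           events = lapply(keep, function(k)
             list(start_s = (starts[k] - 1) / rate,
                  end_s = ends[k] / rate)))
    })
    jsonlite::write_json(list(signals = events),
                         file.path(outDir, "apnea_events.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, cob = cob, template = tmpl, video = video)
}
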