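#' Timestamped thermal video
#'
#' A stack of M x L temperature frames with per-frame timestamps. Frames are
#' stored as an \code{M x L x T} array (rows, columns, frames); temperature
#' values are in arbitrary linear units (degrees Celsius or raw radiometric
#' counts) recorded only in \code{meta$unit}, because every feature used by
#' the detector is relative. After resampling to a uniform grid (see
#' \code{\link{interpolateUniform}}) the meta key \code{uniform_rate} holds
#' the frame rate in Hz.
#'
#' @slot frames numeric array, \code{M x L x T}.
#' @slot timestamps numeric vector of length T, seconds since segment start,
#'   strictly increasing.
#' @slot meta named list of free-form metadata.
#'
#' @seealso \code{\link{readThermalVideo}}, \code{\link{generatePhantom}}
#' @export
setClass("ThermalVideo",
  representation(frames = "array", timestamps = "numeric", meta = "list"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
      return("'frames' must be an M x L x T array")
    if (d[3] < 2L)
      return("a video needs at least 2 frames")
    if (length(object@timestamps) != d[3])
      return("length(timestamps) must equal the number of frames")
    if (anyNA(object@timestamps) || any(diff(object@timestamps) <= 0))
      return("timestamps must be finite and strictly increasing")
    TRUE
  })

#' Construct a ThermalVideo
#'
#' @param frames numeric array \code{M x L x T}.
#' @param timestamps numeric vector of length T, strictly increasing seconds.
#' @param meta named list of metadata (e.g. \code{unit}, \code{segment_id}).
#' @return A validated \code{\linkS4class{ThermalVideo}}.
#' @examples
#' v <- ThermalVideo(array(20, c(2, 2, 3)), c(0, 0.1, 0.2))
#' frameDim(v); nFrames(v)
#' @export
ThermalVideo <- function(frames, timestamps, meta = list()) {
  new("ThermalVideo", frames = frames, timestamps = as.numeric(timestamps),
      meta = meta)
}

#' @rdname accessors
#' @export
setMethod("frames", "ThermalVideo", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("timestamps", "ThermalVideo", function(x) x@timestamps)

#' @rdname accessors
#' @export
setMethod("videoMeta", "ThermalVideo", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("frameDim", "ThermalVideo", function(x) dim(x@frames)[1:2])

#' @rdname accessors
#' @export
setMethod("nFrames", "ThermalVideo", function(x) dim(x@frames)[3])

setMethod("show", "ThermalVideo", function(object) {
  d <- dim(object@frames)
  ts <- object@timestamps
  cat(sprintf("ThermalVideo: %d x %d pixels, %d frames, %.2f s\n",
              d[1], d[2], d[3], ts[length(ts)] - ts[1]))
  rate <- object@meta$uniform_rate
  if (!is.null(rate)) cat(sprintf("  uniform rate: %g Hz\n", rate))
  else cat(sprintf("  mean rate: %.3f Hz (uneven)\n",
                   (d[3] - 1) / (ts[length(ts)] - ts[1])))
  if (!is.null(object@meta$unit)) cat("  unit:", object@meta$unit, "\n")
})

#' Annotated respiratory-flow regions
#'
#' Bounding boxes marking frame regions affected by airflow. Boxes are stored
#' 0-based, half-open, as rows \code{(row_start, col_start, row_end,
#' col_end)}: the box covers rows \code{row_start .. row_end - 1} and columns
#' \code{col_start .. col_end - 1} of the 0-indexed frame. This is the single
#' coordinate convention used by all file formats in the package; in-memory
#' pixel sets are 1-based \code{(row, col)} matrices.
#'
#' @slot boxes integer matrix with 4 columns, one box per row.
#' @slot segmentId character scalar naming the video segment.
#' @seealso \code{\link{readAnnotations}}, \code{\link{annotationPixels}}
#' @export
setClass("AnnotationBoxes",
  representation(boxes = "matrix", segmentId = "character"),
  validity = function(object) {
    b <- object@boxes
    if (ncol(b) != 4L) return("'boxes' must have 4 columns")
    if (nrow(b) > 0) {
      if (anyNA(b) || any(b != round(b))) return("box coordinates must be integers")
      if (any(b[, 1] < 0) || any(b[, 2] < 0))
        return("box starts must be >= 0")
      if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
        return("boxes must have positive height and width (half-open ends)")
    }
    TRUE
  })

#' Construct AnnotationBoxes
#'
#' @param boxes matrix (or list of length-4 vectors) of 0-based half-open
#'   boxes \code{(row_start, col_start, row_end, col_end)}.
#' @param segmentId segment identifier.
#' @param dim optional \code{c(M, L)}; when given, boxes are checked to lie
#'   inside the frame.
#' @return An \code{\linkS4class{AnnotationBoxes}} object.
#' @examples
#' AnnotationBoxes(rbind(c(10, 20, 14, 26)), "seg1", dim = c(80, 180))
#' @export
AnnotationBoxes <- function(boxes, segmentId = "segment", dim = NULL) {
  if (is.list(boxes)) boxes <- do.call(rbind, boxes)
  if (is.null(boxes) || length(boxes) == 0)
    boxes <- matrix(integer(0), 0, 4)
  storage.mode(boxes) <- "integer"
  obj <- new("AnnotationBoxes", boxes = boxes, segmentId = segmentId)
  if (!is.null(dim) && nrow(boxes) > 0) {
    if (any(boxes[, 3] > dim[1]) || any(boxes[, 4] > dim[2]))
      stop("annotation box exceeds the ", dim[1], " x ", dim[2], " frame")
  }
  obj
}

#' @rdname accessors
#' @export
setMethod("annotationBoxes", "AnnotationBoxes", function(x) x@boxes)

setMethod("show", "AnnotationBoxes", function(object) {
  cat(sprintf("AnnotationBoxes: %d box(es), segment '%s'\n",
              nrow(object@boxes), object@segmentId))
})

#' Uniformly sampled 1-D respiration trace
#'
#' @slot values numeric vector of samples.
#' @slot rateHz sampling rate in Hz.
#' @slot kind one of \code{"RF"}, \code{"MR"}, \code{"RefRF"},
#'   \code{"reference"}.
#' @slot rrBpm optional numeric vector of per-window respiration-rate
#'   estimates (breaths per minute); may be empty.
#' @export
setClass("SignalTrace",
  representation(values = "numeric", rateHz = "numeric", kind = "character",
                 rrBpm = "numeric"),
  validity = function(object) {
    if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
        object@rateHz <= 0)
      return("'rateHz' must be a single positive number")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      return("'values' must be finite")
    if (!object@kind %in% c("RF", "MR", "RefRF", "reference"))
      return("'kind' must be one of RF, MR, RefRF, reference")
    TRUE
  })

#' Construct a SignalTrace
#'
#' @param values numeric samples.
#' @param rateHz sampling rate in Hz.
#' @param kind signal kind, one of \code{"RF"}, \code{"MR"}, \code{"RefRF"},
#'   \code{"reference"}.
#' @param rrBpm optional per-window RR estimates in BPM.
#' @return A \code{\linkS4class{SignalTrace}}.
#' @export
SignalTrace <- function(values, rateHz, kind = "reference",
                        rrBpm = numeric(0)) {
  new("SignalTrace", values = as.numeric(values), rateHz = rateHz,
      kind = kind, rrBpm = as.numeric(rrBpm))
}

#' @rdname accessors
#' @export
setMethod("signalValues", "SignalTrace", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleRate", "SignalTrace", function(x) x@rateHz)

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("SignalTrace (%s): %d samples at %g Hz (%.1f s)\n",
              object@kind, length(object@values), object@rateHz,
              length(object@values) / object@rateHz))
})

#' One 8-second sliding window of per-pixel signals
#'
#' @slot samples numeric array \code{M x L x N} of per-pixel time samples.
#' @slot j 1-based window index; window \code{j} starts at \code{(j - 1)} s.
#' @slot startS window start time in seconds.
#' @slot rateHz sampling rate (Hz).
#' @seealso \code{\link{slidingWindows}}
#' @export
setClass("WindowView",
  representation(samples = "array", j = "integer", startS = "numeric",
                 rateHz = "numeric"),
  validity = function(object) {
    if (length(dim(object@samples)) != 3L)
      return("'samples' must be an M x L x N array")
    if (object@j < 1L) return("'j' must be >= 1")
    TRUE
  })

setMethod("show", "WindowView", function(object) {
  d <- dim(object@samples)
  cat(sprintf("WindowView j=%d: %d x %d pixels, N=%d samples from %.1f s\n",
              object@j, d[1], d[2], d[3], object@startS))
})

#' Per-window feature maps
#'
#' The five maps combined into the flow map, plus the raw correlation map.
#' \code{G} is a binary edge map; \code{Qnorm} (pseudo-periodicity) and
#' \code{Wnorm} (RR clusters) are normalized to [0, 1] per window; \code{C}
#' is the Pearson correlation map against the mixed-respiratory core-pixel
#' (values in [-1, 1]); \code{Cbin} its binarization at threshold
#' \code{xi1}; \code{CflowNorm} the signed covariance map against the
#' previous window's flow-core-pixel, normalized to [-1, 1] (all ones for
#' the first window, where no previous core exists).
#'
#' @slot G,Qnorm,Wnorm,C,Cbin,CflowNorm numeric M x L matrices.
#' @slot windowJ window index.
#' @export
setClass("FeatureMaps",
  representation(G = "matrix", Qnorm = "matrix", Wnorm = "matrix",
                 C = "matrix", Cbin = "matrix", CflowNorm = "matrix",
                 windowJ = "integer"))

setMethod("show", "FeatureMaps", function(object) {
  cat(sprintf("FeatureMaps for window %d (%d x %d)\n", object@windowJ,
              nrow(object@G), ncol(object@G)))
})

#' Bank of complex Gabor kernels
#'
#' One quadrature-pair (complex) kernel per combination of wavelength
#' \code{lambda} (pixels per cycle) and orientation \code{theta} (degrees).
#'
#' @slot kernels list of complex matrices with odd spatial support.
#' @slot lambdas numeric vector of wavelengths.
#' @slot thetas numeric vector of orientations in degrees.
#' @seealso \code{\link{makeGaborBank}}
#' @export
setClass("GaborBank",
  representation(kernels = "list", lambdas = "numeric", thetas = "numeric"),
  validity = function(object) {
    if (length(object@kernels) !=
        length(object@lambdas) * length(object@thetas))
      return("need one kernel per (lambda, theta) pair")
    odd <- vapply(object@kernels, function(k) all(dim(k) %% 2L == 1L),
                  logical(1))
    if (!all(odd)) return("kernels must have odd spatial support")
    TRUE
  })

setMethod("show", "GaborBank", function(object) {
  cat(sprintf("GaborBank: %d kernels (%d wavelengths x %d orientations)\n",
              length(object@kernels), length(object@lambdas),
              length(object@thetas)))
})

#' Result of the respiratory-flow pixel detection
#'
#' @slot pflow list (one entry per window) of 1-based \code{(row, col)}
#'   matrices: the detected RF pixel set of each window. Window 1 holds the
#'   single flow-core-pixel; later windows hold the supra-threshold flow-map
#'   pixels, or (fallback) the previous window's set when no pixel passes.
#' @slot pm list of per-window mixed-respiratory pixel sets (same layout).
#' @slot coreTrajectory integer matrix (windows x 2) of flow-core-pixel
#'   positions.
#' @slot mrCoreTrajectory integer matrix of mixed-respiratory core-pixel
#'   positions (NA rows where no candidate existed).
#' @slot fallback logical per window: TRUE where the previous RF set was
#'   carried over.
#' @slot rfSignal,mrSignal \code{\linkS4class{SignalTrace}} objects stitched
#'   across windows.
#' @slot windowStartS numeric vector of window start times.
#' @slot maps optional list of \code{\linkS4class{FeatureMaps}} (only kept on
#'   request) and binarized flow maps.
#' @seealso \code{\link{detectRfPixels}}, \code{\link{analyzeVideo}}
#' @export
setClass("FlowDetectionResult",
  representation(pflow = "list", pm = "list", coreTrajectory = "matrix",
                 mrCoreTrajectory = "matrix", fallback = "logical",
                 rfSignal = "SignalTrace", mrSignal = "SignalTrace",
                 windowStartS = "numeric", maps = "list"))

#' @rdname accessors
#' @export
setMethod("rfPixels", "FlowDetectionResult", function(x) x@pflow)

#' @rdname accessors
#' @export
setMethod("coreTrajectory", "FlowDetectionResult",
          function(x) x@coreTrajectory)

#' @rdname accessors
#' @export
setMethod("rfSignal", "FlowDetectionResult", function(x) x@rfSignal)

setMethod("show", "FlowDetectionResult", function(object) {
  nw <- length(object@pflow)
  sizes <- vapply(object@pflow, nrow, integer(1))
  cat(sprintf(
    "FlowDetectionResult: %d windows, |Pflow| median %d (range %d-%d), %d fallback window(s)\n",
    nw, as.integer(stats::median(sizes)), min(sizes), max(sizes),
    sum(object@fallback)))
})

#' Cessation-of-breathing detection result
#'
#' @slot detection logical per-sample mask (TRUE inside a detected cessation).
#' @slot shortStd numeric per-window short-term standard deviation (8 s
#'   windows, 1 s hop).
#' @slot longStd numeric per-window long-term standard deviation: the median
#'   of the short-term values inside a trailing 15 s window (NA until enough
#'   history exists).
#' @slot windowStartS window start times in seconds.
#' @slot alpha detection threshold ratio: a window is flagged when
#'   \code{shortStd < alpha * longStd}.
#' @slot rateHz sample rate of the input signal.
#' @seealso \code{\link{cobDetect}}
#' @export
setClass("CobResult",
  representation(detection = "logical", shortStd = "numeric",
                 longStd = "numeric", windowStartS = "numeric",
                 alpha = "numeric", rateHz = "numeric"))

#' @rdname accessors
#' @export
setMethod("cobMask", "CobResult", function(x) x@detection)

setMethod("show", "CobResult", function(object) {
  cat(sprintf(
    "CobResult: %d samples, %.1f s flagged (alpha = %g)\n",
    length(object@detection), sum(object@detection) / object@rateHz,
    object@alpha))
})
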