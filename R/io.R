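#' Read and write the thermal-video container
#'
#' The container is a single binary file holding named arrays: a magic line
#' (\code{THVID1}), one JSON header line describing the arrays (name, dtype,
#' dims) and the metadata, then the raw little-endian array payloads in
#' header order. \code{frames} is stored as 32-bit floats and
#' \code{timestamps} as 64-bit floats, so the round trip is lossless for
#' values representable in 32 bits. Extra named arrays (e.g. the phantom's
#' ground-truth masks) ride along as 32-bit floats.
#'
#' @param path file path.
#' @param video a \code{\linkS4class{ThermalVideo}}.
#' @param extras named list of additional numeric arrays to store.
#' @return \code{readThermalVideo} returns a validated
#'   \code{\linkS4class{ThermalVideo}}; extra arrays are attached to
#'   \code{videoMeta(video)$extras}. \code{writeThermalVideo} returns
#'   \code{path} invisibly.
#' @examples
#' v <- ThermalVideo(array(round(rnorm(12), 3), c(2, 2, 3)), c(0, 0.1, 0.2))
#' f <- tempfile(fileext = ".thv")
#' writeThermalVideo(v, f)
#' identical(frames(readThermalVideo(f)), frames(readThermalVideo(f)))
#' @export
readThermalVideo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "THVID1"))
    stop("not a thermal-video container (bad magic): ", path)
  header <- jsonlite::fromJSON(readLines(con, n = 1L),
                               simplifyVector = TRUE)
  arrs <- header$arrays
  if (is.null(arrs) || !all(c("frames", "timestamps") %in% arrs$name))
    stop("container misses required arrays 'frames'/'timestamps'")
  data <- list()
  for (i in seq_len(nrow(arrs))) {
    dims <- unlist(arrs$dims[i])
    n <- prod(dims)
    size <- if (arrs$dtype[i] == "float64") 8L else 4L
    vals <- readBin(con, "double", n = n, size = size, endian = "little")
    if (length(vals) < n) stop("container truncated: array ", arrs$name[i])
    if (length(dims) > 1L) dim(vals) <- dims
    data[[arrs$name[i]]] <- vals
  }
  meta <- header$meta
  meta <- if (is.null(meta)) list() else as.list(meta)
  extras <- data[setdiff(names(data), c("frames", "timestamps"))]
  if (length(extras)) meta$extras <- extras
  ThermalVideo(data$frames, data$timestamps, meta = meta)
}

#' @rdname readThermalVideo
#' @export
writeThermalVideo <- function(video, path, extras = list()) {
  stopifnot(is(video, "ThermalVideo"))
  validObject(video)
  arrs <- data.frame(name = c("frames", "timestamps"),
                     dtype = c("float32", "float64"),
                     stringsAsFactors = FALSE)
  arrs$dims <- c(list(dim(video@frames)), list(length(video@timestamps)))
  for (nm in names(extras)) {
    arrs <- rbind(arrs, data.frame(name = nm, dtype = "float32",
                                   dims = I(list(dim(extras[[nm]]))),
                                   stringsAsFactors = FALSE))
  }
  meta <- video@meta
  meta$extras <- NULL
  header <- jsonlite::toJSON(list(arrays = arrs, meta = meta),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("THVID1", header), con)
  writeBin(as.numeric(video@frames), con, size = 4L, endian = "little")
  writeBin(as.numeric(video@timestamps), con, size = 8L, endian = "little")
  for (nm in names(extras))
    writeBin(as.numeric(extras[[nm]]), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read and write annotation boxes
#'
#' Annotations are stored as JSON:
#' \code{{"segment_id": "...", "boxes": [[r0, c0, r1, c1], ...]}} with
#' 0-based half-open boxes (see \code{\linkS4class{AnnotationBoxes}}).
#'
#' @param path JSON file path.
#' @param boxes an \code{\linkS4class{AnnotationBoxes}} object.
#' @param dim optional \code{c(M, L)} frame size for bounds validation on
#'   read.
#' @return \code{readAnnotations} returns
#'   \code{\linkS4class{AnnotationBoxes}}; \code{writeAnnotations} returns
#'   \code{path} invisibly.
#' @export
readAnnotations <- function(path, dim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  boxes <- obj$boxes
  if (is.list(boxes)) boxes <- do.call(rbind, boxes)
  if (is.null(boxes)) boxes <- matrix(integer(0), 0, 4)
  if (is.vector(boxes)) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  AnnotationBoxes(boxes, segmentId = obj$segment_id %||% "segment",
                  dim = dim)
}

#' @rdname readAnnotations
#' @export
writeAnnotations <- function(boxes, path) {
  stopifnot(is(boxes, "AnnotationBoxes"))
  validObject(boxes)
  b <- boxes@boxes
  blist <- lapply(seq_len(nrow(b)), function(i) as.integer(b[i, ]))
  jsonlite::write_json(list(segment_id = boxes@segmentId, boxes = blist),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixels covered by annotation boxes
#'
#' Expands the 0-based half-open boxes into the in-memory 1-based
#' \code{(row, col)} pixel set \eqn{P_{ann}} (union over boxes, duplicates
#' removed).
#'
#' @param boxes an \code{\linkS4class{AnnotationBoxes}} object.
#' @param dim \code{c(M, L)} frame size (bounds check).
#' @return Integer matrix with columns \code{row}, \code{col} (1-based).
#' @examples
#' a <- AnnotationBoxes(rbind(c(10, 20, 14, 26)), "s")
#' nrow(annotationPixels(a, c(80, 180)))  # 4 x 6 = 24 pixels
#' @export
annotationPixels <- function(boxes, dim) {
  b <- boxes@boxes
  if (nrow(b) > 0 && (any(b[, 3] > dim[1]) || any(b[, 4] > dim[2])))
    stop("annotation box exceeds the ", dim[1], " x ", dim[2], " frame")
  px <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(nrow(b))) {
    rows <- (b[i, 1] + 1L):b[i, 3]
    cols <- (b[i, 2] + 1L):b[i, 4]
    px <- rbind(px, as.matrix(expand.grid(row = rows, col = cols)))
  }
  px[!duplicated(pixelKeys(px)), , drop = FALSE]
}

#' Read and write signal traces as CSV
#'
#' CSV with header \code{t_s,value} and, when per-window RR estimates are
#' present, a third column \code{rr_bpm} (NA-padded to the sample count).
#'
#' @param path CSV file path.
#' @param trace a \code{\linkS4class{SignalTrace}}.
#' @param kind signal kind used when reading.
#' @return \code{readSignalTrace} returns a
#'   \code{\linkS4class{SignalTrace}}; \code{writeSignalTrace} returns
#'   \code{path} invisibly.
#' @export
readSignalTrace <- function(path, kind = "reference") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(df)))
    stop("signal CSV needs columns t_s,value")
  dt <- diff(df$t_s)
  rate <- 1 / stats::median(dt)
  rr <- if ("rr_bpm" %in% names(df)) df$rr_bpm[!is.na(df$rr_bpm)] else numeric(0)
  SignalTrace(df$value, rateHz = rate, kind = kind, rrBpm = rr)
}

#' @rdname readSignalTrace
#' @export
writeSignalTrace <- function(trace, path) {
  stopifnot(is(trace, "SignalTrace"))
  n <- length(trace@values)
  df <- data.frame(t_s = sprintf("%.10g", (seq_len(n) - 1) / trace@rateHz),
                   value = sprintf("%.10g", trace@values))
  if (length(trace@rrBpm)) {
    rr <- rep(NA_real_, n)
    rr[seq_along(trace@rrBpm)] <- trace@rrBpm
    df$rr_bpm <- ifelse(is.na(rr), "", sprintf("%.10g", rr))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
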