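#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x An object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("videoMeta", function(x) standardGeneric("videoMeta"))

#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("annotationBoxes", function(x) standardGeneric("annotationBoxes"))

#' @rdname accessors
#' @export
setGeneric("rfPixels", function(x) standardGeneric("rfPixels"))

#' @rdname accessors
#' @export
setGeneric("coreTrajectory", function(x) standardGeneric("coreTrajectory"))

#' @rdname accessors
#' @export
setGeneric("rfSignal", function(x) standardGeneric("rfSignal"))

#' @rdname accessors
#' @export
setGeneric("cobMask", function(x) standardGeneric("cobMask"))
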