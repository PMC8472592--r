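#' Pixel-level flow-detection score PF
#'
#' Percentage of the detected RF pixels that lie inside the annotated RF
#' regions: \code{100 * |Pflow intersect Pann| / |Pflow|}.
#'
#' @param pflow 1-based \code{(row, col)} matrix of detected RF pixels
#'   (non-empty; the detector's fallback rule guarantees this).
#' @param pann 1-based \code{(row, col)} matrix of annotated RF pixels (see
#'   \code{\link{annotationPixels}}).
#' @return Percentage in [0, 100].
#' @export
pfMetric <- function(pflow, pann) {
  if (is.null(pflow) || nrow(pflow) == 0)
    stop("empty Pflow (upstream contract violation)")
  100 * sum(pixelKeys(pflow) %in% pixelKeys(pann)) / nrow(pflow)
}

#' Pixel-level motion-contamination score PM
#'
#' Percentage of the detected RF pixels that belong to the
#' mixed-respiratory pixel set after the annotated RF pixels are removed
#' from it: \code{100 * |Pflow intersect (Pm - Pann)| / |Pflow|}. Estimates
#' how many motion pixels leaked into the flow set.
#'
#' @inheritParams pfMetric
#' @param pm 1-based \code{(row, col)} matrix of mixed-respiratory pixels.
#' @return Percentage in [0, 100].
#' @export
pmMetric <- function(pflow, pm, pann) {
  if (is.null(pflow) || nrow(pflow) == 0)
    stop("empty Pflow (upstream contract violation)")
  mOnly <- setdiff(pixelKeys(pm), pixelKeys(pann))
  100 * sum(pixelKeys(pflow) %in% mOnly) / nrow(pflow)
}

#' Per-segment aggregation of pixel scores
#'
#' Unweighted mean of the per-window PF and PM percentages over a video
#' segment. Window 1 (where the RF set is the single flow-core-pixel) is
#' included by default, matching the per-window score definition; set
#' \code{dropFirst = TRUE} to exclude it.
#'
#' @param result a \code{\linkS4class{FlowDetectionResult}} (or a list of
#'   per-window pixel matrices via \code{pflowList}/\code{pmList}).
#' @param pann annotated RF pixel matrix.
#' @param pflowList,pmList optional explicit per-window pixel sets.
#' @param dropFirst exclude window 1 from the means.
#' @return List with \code{perWindow} (data.frame \code{window_j, pf, pm})
#'   and scalar \code{pf}, \code{pm} segment means.
#' @export
aggregateScores <- function(result = NULL, pann, pflowList = NULL,
                            pmList = NULL, dropFirst = FALSE) {
  if (!is.null(result)) {
    pflowList <- result@pflow
    pmList <- result@pm
  }
  nw <- length(pflowList)
  pf <- vapply(seq_len(nw), function(j) pfMetric(pflowList[[j]], pann),
               numeric(1))
  pmv <- vapply(seq_len(nw), function(j)
    pmMetric(pflowList[[j]], pmList[[j]], pann), numeric(1))
  keep <- if (dropFirst && nw > 1) 2:nw else seq_len(nw)
  list(perWindow = data.frame(window_j = seq_len(nw), pf = pf, pm = pmv),
       pf = mean(pf[keep]), pm = mean(pmv[keep]))
}
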