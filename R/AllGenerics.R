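## Accessor generics. Slot access stays internal; these are the public surface.

#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @export
setGeneric("effectiveGenomeSize",
           function(x) standardGeneric("effectiveGenomeSize"))
#' @export
setGeneric("fastaPath", function(x) standardGeneric("fastaPath"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))
#' @export
setGeneric("replicateLabel", function(x) standardGeneric("replicateLabel"))
#' @export
setGeneric("spikeInFragments", function(x) standardGeneric("spikeInFragments"))

#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @export
setGeneric("fraction", function(x) standardGeneric("fraction"))
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @export
setGeneric("kind", function(x) standardGeneric("kind"))
#' @export
setGeneric("summits", function(x) standardGeneric("summits"))
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @export
setGeneric("normState", function(x) standardGeneric("normState"))
#' @export
setGeneric("pseudocount", function(x) standardGeneric("pseudocount"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("lowSet", function(x) standardGeneric("lowSet"))
#' @export
setGeneric("highSet", function(x) standardGeneric("highSet"))
#' @export
setGeneric("cutoffCurve", function(x) standardGeneric("cutoffCurve"))

#' Classify positions by accessibility or stability
#'
#' @param x a \code{ScoreTable} (or a bare numeric score vector).
#' @param ... passed on to \code{\link{rankSlopeCutoffs}}.
#' @export
setGeneric("classifyAccessibility",
           function(x, ...) standardGeneric("classifyAccessibility"))
#' @rdname classifyAccessibility
#' @export
setGeneric("classifyStability",
           function(x, ...) standardGeneric("classifyStability"))
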